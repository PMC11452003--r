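#' Experiment configuration
#'
#' Bundles every knob of the phantom experiment: the training/testing
#' phantom families, the corruption applied to test predictions, shape
#' model, registration, 2D and CRF settings, and the evaluation label list.
#' All seeds are explicit so the whole experiment is a pure function of the
#' config.
#'
#' @param phantom a `phantom_spec` for the training family (and, with
#'   `test_seed`, the testing family).
#' @param corruption a `corruption_spec`.
#' @param n_test number of corrupted test subjects.
#' @param test_seed seed offset of the testing family.
#' @param particles,ssm_seed shape model settings.
#' @param ns,lambda registration settings.
#' @param slice2d a `slice2d_params`.
#' @param crf a `crf_params`.
#' @param crf_flip_prob unary corruption used for the CRF arm.
#' @param arms post-processing arms to run.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              corruption = corruption_spec(),
                              n_test = 8, test_seed = 1000,
                              particles = 256, ssm_seed = 0,
                              ns = 5, lambda = "auto",
                              slice2d = slice2d_params(),
                              crf = crf_params(),
                              crf_flip_prob = 0.05,
                              arms = c("raw", "2d", "crf", "ms")) {
  structure(list(phantom = phantom, corruption = corruption,
                 n_test = n_test, test_seed = test_seed,
                 particles = particles, ssm_seed = ssm_seed,
                 ns = ns, lambda = lambda, slice2d = slice2d, crf = crf,
                 crf_flip_prob = crf_flip_prob, arms = arms),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; nested
#' `phantom`, `corruption`, `slice2d` and `crf` blocks mirror the
#' respective constructors.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$corruption)) args$corruption <- do.call(corruption_spec, y$corruption)
  if (!is.null(y$slice2d)) args$slice2d <- do.call(slice2d_params, y$slice2d)
  if (!is.null(y$crf)) args$crf <- do.call(crf_params, y$crf)
  for (k in c("n_test", "test_seed", "particles", "ssm_seed", "ns", "lambda",
              "crf_flip_prob", "arms"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(experiment_config, args)
}

# corrupted unaries for the CRF arm of one subject
crf_arm_inputs <- function(gt, corrupted, flip_prob, seed) {
  n_classes <- max(gt$grid) + 1L
  means <- seq(20, by = 60, length.out = n_classes)
  img <- synth_intensity_image(gt, means, noise_sd = 5, seed = seed)
  u <- unaries_from_labels(corrupted, max(flip_prob, 1e-3), n_classes)
  list(unaries = u, image = img)
}

#' Run the phantom experiment end to end
#'
#' Generates a training family, builds the per-label shape model bank,
#' generates corrupted test predictions, runs the requested post-processing
#' arms (raw prediction, 2D morphology, CRF, mean shape), evaluates every
#' arm against the ground truth and pairs the arms with Wilcoxon
#' signed-rank tests per metric. All arms share the same corrupted inputs
#' per subject (paired design).
#'
#' @param cfg an `experiment_config`.
#' @param out_dir optional directory: volumes and the manifest are written
#'   there as NIfTI / JSON.
#' @param progress print stage-tagged progress lines.
#' @return list with `metrics` (long data.frame: subject, arm, label,
#'   dsc/rve/hd/assd), `tests` (pairwise Wilcoxon p-values vs raw),
#'   `bank`, and `manifest` (all seeds and parameters).
#' @export
run_experiment <- function(cfg, out_dir = NULL, progress = interactive()) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(stage, fmt, ...) {
    if (progress) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  multi <- cfg$phantom$labels >= 2

  say("train", "generating training family (n=%d)", cfg$phantom$n_subjects)
  if (multi) {
    train_vols <- lapply(seq_len(cfg$phantom$n_subjects), function(s) {
      sp <- cfg$phantom; sp$seed <- sp$seed + s - 1
      generate_multilabel_phantom(sp)
    })
    training <- lapply(seq_len(cfg$phantom$labels), function(l)
      lapply(train_vols, extract_label_mask, label = l))
    bank_labels <- seq_len(cfg$phantom$labels)
  } else {
    sp <- cfg$phantom
    fam <- generate_shape_family(sp)
    training <- list(fam)
    bank_labels <- 1L
  }
  say("ssm", "building shape models (%d particles)", cfg$particles)
  bank <- build_model_bank(training, labels = bank_labels,
                           particles = cfg$particles, seed = cfg$ssm_seed)

  say("test", "generating %d corrupted test subjects", cfg$n_test)
  rows <- list()
  for (s in seq_len(cfg$n_test)) {
    sp <- cfg$phantom
    sp$seed <- cfg$test_seed + s - 1
    gt <- if (multi) generate_multilabel_phantom(sp) else {
      sp$n_subjects <- 1
      label_volume(array(as.integer(generate_shape_family(sp)[[1]]$grid),
                         sp$shape))
    }
    cs <- cfg$corruption
    cs$seed <- cfg$corruption$seed + s - 1
    pred <- corrupt_prediction(gt, cs)
    arms_out <- list(raw = pred)
    if ("2d" %in% cfg$arms)
      arms_out[["2d"]] <- postprocess_2d_volume(pred, cfg$slice2d)
    if ("crf" %in% cfg$arms) {
      inp <- crf_arm_inputs(gt, pred, cfg$crf_flip_prob, seed = cs$seed)
      arms_out[["crf"]] <- crf_postprocess_volume(inp$unaries, inp$image,
                                                  cfg$crf)
    }
    if ("ms" %in% cfg$arms)
      arms_out[["ms"]] <- ms_postprocess_volume(pred, bank, ns = cfg$ns,
                                                lambda = cfg$lambda)
    for (arm in names(arms_out)) {
      rep <- pooled_metrics(gt, arms_out[[arm]], labels = bank_labels)
      rep$subject <- s
      rep$arm <- arm
      rows[[length(rows) + 1]] <- rep
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_label_volume(gt, file.path(out_dir, sprintf("gt_%02d.nii.gz", s)))
      for (arm in names(arms_out))
        write_label_volume(arms_out[[arm]],
                           file.path(out_dir, sprintf("%s_%02d.nii.gz", arm, s)))
    }
    say("eval", "subject %d/%d done", s, cfg$n_test)
  }
  metrics <- do.call(rbind, rows)

  tests <- list()
  arms_run <- setdiff(unique(metrics$arm), "raw")
  for (arm in arms_run)
    for (mt in c("dsc", "rve", "hd", "assd")) {
      a <- metrics[metrics$arm == arm & metrics$label != "pooled", mt]
      b <- metrics[metrics$arm == "raw" & metrics$label != "pooled", mt]
      ok <- is.finite(a) & is.finite(b)
      p <- tryCatch(wilcoxon_signed_rank(a[ok], b[ok])$p.value,
                    error = function(e) NA_real_)
      tests[[length(tests) + 1]] <- data.frame(arm = arm, metric = mt,
                                               p.value = p)
    }
  tests <- do.call(rbind, tests)

  manifest <- list(phantom = unclass(cfg$phantom),
                   corruption = unclass(cfg$corruption),
                   n_test = cfg$n_test, test_seed = cfg$test_seed,
                   particles = cfg$particles, ssm_seed = cfg$ssm_seed,
                   ns = cfg$ns, lambda = cfg$lambda,
                   slice2d = unclass(cfg$slice2d), crf = unclass(cfg$crf),
                   arms = cfg$arms)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  list(metrics = metrics, tests = tests, bank = bank, manifest = manifest)
}
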
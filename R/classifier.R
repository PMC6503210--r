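#' Train the two-class heatmap classifier
#'
#' A small feed-forward neural network (one hidden layer, sigmoid
#' output, binary cross-entropy loss, via \pkg{nnet}) mapping the
#' flattened heatmap (one input per LED, 200 at the default grid) to a
#' score in `[0, 1]`: the "trust value", read as healthy below 0.5 and
#' predisposed to type 2 diabetes above. `method = "logistic"` fits the
#' no-hidden-layer (logistic regression) fallback. Training regimes
#' mirror the cohort splits: all subjects, female only, or male only
#' (using each heatmap's `group` field). Deterministic under a fixed
#' seed.
#'
#' @param heatmaps List of `ppc_heatmap` with `label` set (`"healthy"`
#'   or `"diabetes"`); `group` is used by the female/male regimes.
#' @param seed Integer seed for weight initialisation.
#' @param hidden Hidden-layer size (default 8, ample for 200-input
#'   heatmaps and small cohorts; ignored for
#'   `"logistic"`).
#' @param method `"nnet"` (default) or `"logistic"`.
#' @param regime `"all"` (default), `"female"` or `"male"`.
#' @param maxit,decay Optimiser iterations and weight decay.
#' @return A `ppc_classifier`: list with the fitted model and training
#'   metadata (`seed`, `regime`, `n_train`, `cohort_sizes`,
#'   `input_dim`).
#' @export
train_classifier <- function(heatmaps, seed = 1L, hidden = 8L,
                             method = c("nnet", "logistic"),
                             regime = c("all", "female", "male"),
                             maxit = 300L, decay = 0.01) {
  method <- match.arg(method)
  regime <- match.arg(regime)
  if (regime != "all") {
    grp <- vapply(heatmaps, function(h)
      if (is.null(h$group)) NA_character_ else h$group, character(1))
    heatmaps <- heatmaps[!is.na(grp) & grp == regime]
  }
  if (length(heatmaps) < 2)
    ppc_stop("training", "regime '%s' leaves %d heatmap(s); need >= 2",
             regime, length(heatmaps))
  labs <- vapply(heatmaps, function(h) {
    if (is.null(h$label)) ppc_stop("training", "all heatmaps must carry a label")
    h$label
  }, character(1))
  y <- as.numeric(labs == "diabetes")
  if (length(unique(y)) < 2)
    ppc_stop("training", "training needs both classes; got only '%s'",
             unique(labs))
  x <- t(vapply(heatmaps, function(h) as.vector(t(h$values)),
                numeric(length(heatmaps[[1]]$values))))
  fit <- with_local_seed(seed, {
    if (method == "nnet")
      nnet::nnet(x, y, size = hidden, entropy = TRUE, decay = decay,
                 maxit = maxit, trace = FALSE,
                 MaxNWts = (ncol(x) + 1L) * hidden + hidden + 1L + 10L)
    else
      nnet::nnet(x, y, size = 0, skip = TRUE, entropy = TRUE,
                 decay = decay, maxit = maxit, trace = FALSE,
                 MaxNWts = ncol(x) + 10L)
  })
  cohort <- table(labs, vapply(heatmaps, function(h)
    if (is.null(h$group)) "unknown" else h$group, character(1)))
  structure(list(fit = fit, method = method, seed = as.integer(seed),
                 hidden = if (method == "nnet") as.integer(hidden) else 0L,
                 regime = regime, n_train = length(heatmaps),
                 cohort_sizes = cohort, input_dim = ncol(x)),
            class = "ppc_classifier")
}

#' Score a heatmap and classify it
#'
#' `predict_heatmap()` returns the trust value in `[0, 1]`;
#' `classify_score()` applies the 50% threshold: below 0.5 `"healthy"`,
#' above 0.5 `"predisposed"`, exactly 0.5 `"indeterminate"` (the
#' threshold itself belongs to neither class).
#'
#' @param model A `ppc_classifier`.
#' @param h A `ppc_heatmap` whose flattened length equals the model's
#'   input dimension.
#' @return `predict_heatmap()`: numeric score in `[0, 1]`.
#'   `classify_score()`: character class.
#' @export
predict_heatmap <- function(model, h) {
  v <- as.vector(t(h$values))
  if (length(v) != model$input_dim)
    ppc_stop("input", "heatmap has %d cells, model expects %d",
             length(v), model$input_dim)
  s <- as.numeric(stats::predict(model$fit, matrix(v, nrow = 1)))
  min(max(s, 0), 1)
}

#' @rdname predict_heatmap
#' @param score Trust value in `[0, 1]`.
#' @export
classify_score <- function(score) {
  if (score < 0.5) "healthy"
  else if (score > 0.5) "predisposed"
  else "indeterminate"
}

#' Generate a synthetic labeled cohort of heatmaps
#'
#' Emulates the study cohort structure — by default 5 healthy female,
#' 8 diabetic female, 13 healthy male and 10 diabetic male subjects
#' (36 heatmaps) — as draws around class-mean patterns. Each subject's
#' heatmap is the class mean plus smooth per-subject variation and
#' per-cell noise; the diabetic class mean adds `separation` on a
#' spatial contrast pattern, so `separation = 0` yields an
#' information-free cohort for null checks.
#'
#' @param sizes Named integer vector
#'   `c(healthy_female, diabetic_female, healthy_male, diabetic_male)`.
#' @param n_rows,n_cols Heatmap grid (default 10 x 20).
#' @param separation Class-mean contrast amplitude in heatmap units
#'   (default 0.2).
#' @param subject_sd Per-subject smooth offset sd (default 0.03).
#' @param noise_sd Per-cell noise sd (default 0.05).
#' @param seed Integer seed.
#' @return List of labeled `ppc_heatmap`.
#' @export
synthetic_cohort <- function(sizes = c(healthy_female = 5L,
                                       diabetic_female = 8L,
                                       healthy_male = 13L,
                                       diabetic_male = 10L),
                             n_rows = 10L, n_cols = 20L,
                             separation = 0.2, subject_sd = 0.03,
                             noise_sd = 0.05, seed = 1L) {
  if (is.null(names(sizes)) || !all(grepl("_(fe)?male$", names(sizes))))
    ppc_stop("invalid_config",
             "'sizes' must be named like healthy_female, diabetic_male, ...")
  with_local_seed(seed, {
    # smooth left/right contrast pattern carrying the class difference
    pat <- outer(seq_len(n_rows), seq_len(n_cols), function(r, c)
      sin(pi * r / (n_rows + 1)) * (c - (n_cols + 1) / 2) / n_cols)
    pat <- pat / max(abs(pat))
    out <- list()
    sid <- 0L
    for (k in seq_along(sizes)) {
      nm <- names(sizes)[k]
      lab <- if (grepl("^healthy", nm)) "healthy" else "diabetes"
      grp <- sub("^[a-z]+_", "", nm)
      for (i in seq_len(sizes[[k]])) {
        sid <- sid + 1L
        base <- 0.45 + stats::rnorm(1, sd = subject_sd)
        v <- base + (lab == "diabetes") * separation * pat +
          matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
        v <- pmin(pmax(v, 0), 1)
        out[[sid]] <- heatmap_matrix(v, n_frames_averaged = 20L,
                                     subject_id = sprintf("S%03d", sid),
                                     label = lab, group = grp)
      }
    }
    out
  })
}

#' Load a cohort of labeled heatmaps from a directory
#'
#' Reads every `*.csv` heatmap grid in `dir`; metadata comes from the
#' filename convention `<id>_<label>_<group>.csv`, e.g.
#' `S001_healthy_female.csv`.
#'
#' @param dir Directory of heatmap CSV files.
#' @return List of `ppc_heatmap` with `subject_id`, `label`, `group`.
#' @export
load_cohort <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(paths) == 0L)
    ppc_stop("format", "no heatmap CSV files found in '%s'", dir)
  lapply(paths, function(p) {
    parts <- strsplit(sub("\\.csv$", "", basename(p)), "_")[[1]]
    if (length(parts) < 3)
      ppc_stop("format",
               "cohort filename '%s' is not <id>_<label>_<group>.csv",
               basename(p))
    h <- load_heatmap(p)
    h$subject_id <- parts[1]; h$label <- parts[2]; h$group <- parts[3]
    if (!h$label %in% c("healthy", "diabetes"))
      ppc_stop("format", "label in '%s' must be healthy or diabetes",
               basename(p))
    h
  })
}

#' Save a cohort to a directory of heatmap CSVs
#'
#' @param cohort List of labeled `ppc_heatmap`.
#' @param dir Output directory.
#' @return File paths, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort, function(h) {
    p <- file.path(dir, sprintf("%s_%s_%s.csv", h$subject_id, h$label,
                                if (is.null(h$group)) "unknown" else h$group))
    save_heatmap(h, p)
    p
  }, character(1))
  invisible(paths)
}
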
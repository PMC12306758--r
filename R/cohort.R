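# Synthetic tabular cohort with known ground-truth risk.
#
# Emulates the structure of a screening-trial prostate-cancer mortality
# cohort: rare positive outcome (~7% prevalence), a mix of categorical and
# continuous features, missing entries, and a known logistic ground-truth
# risk function retained for parameter-recovery and calibration tests.

#' Generative law of the synthetic cohort
#'
#' @param n Number of records.
#' @param prevalence Target positive-class frequency (default 0.07).
#' @param cat_levels Integer vector: number of levels of each categorical
#'   feature.
#' @param n_cont Number of continuous (standard normal) features.
#' @param miss_cat,miss_cont Per-feature missing-completely-at-random
#'   rates, recycled across the categorical / continuous features.
#' @param cat_coef List of per-level logit contributions, one numeric
#'   vector per categorical feature (length = level count); `NULL` draws
#'   fixed defaults from the law seed.
#' @param cont_coef Numeric logit slopes of the continuous features;
#'   `NULL` uses defaults.
#' @param seed Integer seed.
#' @return An object of class `cohort_law`.
#' @details The ground-truth logit is linear in the encoded features:
#'   `eta = c0 + sum_j coef_j[level_ij] + sum_k slope_k z_ik`, with the
#'   intercept `c0` calibrated at sampling time so the mean of
#'   `sigmoid(eta)` matches the target prevalence. Missingness is applied
#'   after label generation and independently of the label (MCAR).
#' @export
cohort_law <- function(n = 3600L, prevalence = 0.07,
                       cat_levels = c(3L, 4L, 2L), n_cont = 4L,
                       miss_cat = 0.05, miss_cont = 0.10,
                       cat_coef = NULL, cont_coef = NULL, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (any(cat_levels < 2L)) stop("categorical features need >= 2 levels")
  if (is.null(cat_coef)) {
    # fixed moderate effects, zero-mean within each feature
    cat_coef <- lapply(seq_along(cat_levels), function(j) {
      L <- cat_levels[j]
      v <- seq(-1, 1, length.out = L) * 0.8
      v - mean(v)
    })
  }
  if (is.null(cont_coef)) {
    cont_coef <- c(1.0, -0.7, 0.5, 0.3, rep(0.3, max(0, n_cont - 4L)))[
      seq_len(n_cont)]
  }
  stopifnot(length(cat_coef) == length(cat_levels),
            all(lengths(cat_coef) == cat_levels),
            length(cont_coef) == n_cont)
  law <- list(n = as.integer(n), prevalence = prevalence,
              cat_levels = as.integer(cat_levels), n_cont = as.integer(n_cont),
              miss_cat = rep_len(miss_cat, length(cat_levels)),
              miss_cont = rep_len(miss_cont, n_cont),
              cat_coef = cat_coef, cont_coef = cont_coef,
              seed = as.integer(seed))
  class(law) <- "cohort_law"
  law
}

#' Sample a synthetic cohort
#'
#' Draws features, calibrates the ground-truth intercept to the target
#' prevalence, draws labels from the logistic risk, then applies MCAR
#' missingness. True logits (pre-missingness) are stored on the cohort.
#'
#' @param law A `cohort_law`.
#' @return A `cohort`: features (factors + numerics, `NA` = missing),
#'   labels, `true_logit`, `true_p`, and a schema table.
#' @export
sample_cohort <- function(law) {
  stopifnot(inherits(law, "cohort_law"))
  with_seed(law$seed, {
    n <- law$n
    cat_names <- sprintf("cat%d", seq_along(law$cat_levels))
    cont_names <- sprintf("cont%d", seq_len(law$n_cont))
    feats <- list()
    eta <- numeric(n)
    for (j in seq_along(law$cat_levels)) {
      L <- law$cat_levels[j]
      lev <- sample.int(L, n, replace = TRUE)
      eta <- eta + law$cat_coef[[j]][lev]
      feats[[cat_names[j]]] <- factor(sprintf("L%d", lev),
                                      levels = sprintf("L%d", seq_len(L)))
    }
    for (k in seq_len(law$n_cont)) {
      z <- stats::rnorm(n)
      eta <- eta + law$cont_coef[k] * z
      feats[[cont_names[k]]] <- z
    }
    # calibrate intercept so mean(sigmoid(eta + c0)) == prevalence
    f <- function(c0) mean(stats::plogis(eta + c0)) - law$prevalence
    lo <- -40; hi <- 40
    if (f(lo) > 0 || f(hi) < 0) {
      stop(sprintf(
        "prevalence target %.3f unreachable: attainable range [%.3g, %.3g]",
        law$prevalence, mean(stats::plogis(eta + lo)),
        mean(stats::plogis(eta + hi))))
    }
    c0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    true_logit <- eta + c0
    true_p <- stats::plogis(true_logit)
    y <- stats::rbinom(n, 1L, true_p)
    # MCAR missingness, applied after label generation
    df <- as.data.frame(feats, stringsAsFactors = FALSE)
    for (j in seq_along(law$cat_levels)) {
      if (law$miss_cat[j] > 0) {
        drop <- stats::runif(n) < law$miss_cat[j]
        df[[cat_names[j]]][drop] <- NA
      }
    }
    for (k in seq_len(law$n_cont)) {
      if (law$miss_cont[k] > 0) {
        drop <- stats::runif(n) < law$miss_cont[k]
        df[[cont_names[k]]][drop] <- NA
      }
    }
    structure(list(
      features = df,
      labels = y,
      true_p = true_p,
      true_logit = true_logit,
      schema = data.frame(
        column = c(cat_names, cont_names),
        kind = c(rep("categorical", length(cat_names)),
                 rep("continuous", length(cont_names))),
        stringsAsFactors = FALSE),
      law = law
    ), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d records, %d features, prevalence %.3f>\n",
              length(x$labels), ncol(x$features), mean(x$labels)))
  invisible(x)
}

#' Write / read a cohort as CSV with a schema sidecar
#'
#' The CSV holds one column per feature plus the reserved label column
#' `.label`; missing entries are written as empty fields. The sidecar
#' (YAML) declares each column's kind so the file round-trips without
#' type guessing.
#'
#' @param cohort A `cohort`.
#' @param path CSV path; the sidecar is written to `<path>.schema.yaml`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort` (without generative ground truth).
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$features
  df[[".label"]] <- cohort$labels
  utils::write.csv(df, path, row.names = FALSE, na = "")
  yaml::write_yaml(
    list(label = ".label",
         columns = stats::setNames(as.list(cohort$schema$kind),
                                   cohort$schema$column)),
    paste0(path, ".schema.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  schema <- yaml::read_yaml(paste0(path, ".schema.yaml"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  labels <- as.integer(df[[schema$label]])
  df[[schema$label]] <- NULL
  cols <- names(schema$columns)
  feats <- df[, cols, drop = FALSE]
  for (cn in cols) {
    if (schema$columns[[cn]] == "continuous") {
      feats[[cn]] <- as.numeric(feats[[cn]])
    } else {
      feats[[cn]] <- factor(feats[[cn]])
    }
  }
  structure(list(
    features = feats,
    labels = labels,
    schema = data.frame(column = cols,
                        kind = unlist(schema$columns, use.names = FALSE),
                        stringsAsFactors = FALSE)
  ), class = "cohort")
}
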
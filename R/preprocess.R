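# Feature encoding and stratified six-fold 4:1:1 cross-validation plan.

#' Fit a feature encoder on a training subset
#'
#' Categorical features map to one indicator column per level observed in
#' the training rows plus one "missing" indicator; continuous features map
#' to a standardized value column (training-fold mean/sd only, so no
#' statistics leak from validation or test rows) plus a binary missing
#' flag. Missing continuous values are imputed with 0 *after*
#' standardization — the post-standardization mean, the least-informative
#' fill — and flagged.
#'
#' @param cohort A `cohort`.
#' @param train_idx Row indices used to fit levels and statistics.
#' @return An `encoder` object for [encode()].
#' @export
fit_encoder <- function(cohort, train_idx = seq_along(cohort$labels)) {
  schema <- cohort$schema
  spec <- list()
  for (i in seq_len(nrow(schema))) {
    cn <- schema$column[i]
    v <- cohort$features[[cn]][train_idx]
    if (schema$kind[i] == "categorical") {
      lev <- levels(factor(v)) # levels observed in training rows
      spec[[cn]] <- list(kind = "categorical", levels = lev)
    } else {
      obs <- v[!is.na(v)]
      if (length(obs) < 2L) stop(sprintf("feature %s: too few observed", cn))
      s <- stats::sd(obs)
      spec[[cn]] <- list(kind = "continuous", mean = mean(obs),
                         sd = if (s > 0) s else 1)
    }
  }
  structure(list(spec = spec, columns = schema$column), class = "encoder")
}

#' Encode a cohort into a dense numeric design matrix
#'
#' @param encoder An `encoder` from [fit_encoder()].
#' @param cohort A `cohort` (any rows; the encoder's statistics are fixed).
#' @param idx Optional row subset.
#' @return List with the design `matrix`, the `labels` of the encoded
#'   rows, and a `provenance` table mapping each design column back to its
#'   source feature and role (level name, value, or missing flag).
#'   Categorical levels unseen at fit time map to the missing indicator
#'   with a warning.
#' @export
encode <- function(encoder, cohort, idx = seq_along(cohort$labels)) {
  stopifnot(inherits(encoder, "encoder"))
  cols <- list()
  prov_feature <- character()
  prov_role <- character()
  for (cn in encoder$columns) {
    sp <- encoder$spec[[cn]]
    v <- cohort$features[[cn]][idx]
    if (sp$kind == "categorical") {
      ch <- as.character(v)
      unseen <- !is.na(ch) & !(ch %in% sp$levels)
      if (any(unseen)) {
        warning(sprintf("feature %s: %d unseen level value(s) mapped to missing",
                        cn, sum(unseen)))
        ch[unseen] <- NA
      }
      for (lev in sp$levels) {
        cols[[length(cols) + 1L]] <- as.numeric(!is.na(ch) & ch == lev)
        prov_feature <- c(prov_feature, cn)
        prov_role <- c(prov_role, lev)
      }
      cols[[length(cols) + 1L]] <- as.numeric(is.na(ch))
      prov_feature <- c(prov_feature, cn)
      prov_role <- c(prov_role, ".missing")
    } else {
      z <- (as.numeric(v) - sp$mean) / sp$sd
      flag <- as.numeric(is.na(z))
      z[is.na(z)] <- 0
      cols[[length(cols) + 1L]] <- z
      cols[[length(cols) + 1L]] <- flag
      prov_feature <- c(prov_feature, cn, cn)
      prov_role <- c(prov_role, ".value", ".missing_flag")
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste(prov_feature, prov_role, sep = ":")
  list(matrix = X,
       labels = cohort$labels[idx],
       provenance = data.frame(column = colnames(X), feature = prov_feature,
                               role = prov_role, stringsAsFactors = FALSE))
}

#' Stratified six-fold 4:1:1 split plan
#'
#' Permutes each class separately, cuts the permutation into six blocks,
#' and assigns block `f` as fold `f`'s test set, block `f + 1` (cyclic) as
#' its validation set and the remaining four blocks as training — a 4:1:1
#' ratio with pairwise-disjoint test sets covering all records and the
#' positive-class frequency conserved in every subset up to rounding.
#'
#' @param labels Binary 0/1 labels.
#' @param seed Integer seed.
#' @param n_folds Number of folds (default 6).
#' @return A `split_plan`: list of folds, each with `train`, `validation`,
#'   `test` index vectors.
#' @export
make_splits <- function(labels, seed, n_folds = 6L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 2L * n_folds) stop("too few records to stratify")
  counts <- table(factor(labels, levels = 0:1))
  if (any(counts < n_folds)) {
    stop(sprintf("each class needs >= %d members to stratify %d test folds",
                 n_folds, n_folds))
  }
  blocks <- with_seed(seed, {
    bl <- rep(list(integer()), n_folds)
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      grp <- rep(seq_len(n_folds), length.out = length(idx))
      # contiguous blocks of the permutation, sizes as equal as possible
      grp <- sort(grp)
      for (f in seq_len(n_folds)) {
        bl[[f]] <- c(bl[[f]], idx[grp == f])
      }
    }
    lapply(bl, sort)
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    val_b <- if (f == n_folds) 1L else f + 1L
    list(test = blocks[[f]],
         validation = blocks[[val_b]],
         train = sort(unlist(blocks[setdiff(seq_len(n_folds),
                                            c(f, val_b))])))
  })
  structure(list(folds = folds, n = n, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds[[1]], length, integer(1))
  cat(sprintf("<split_plan: %d folds over %d records; train/val/test = %s>\n",
              length(x$folds), x$n, paste(sizes[c("train", "validation",
                                                  "test")], collapse = "/")))
  invisible(x)
}

#' Serialize / restore a split plan as JSON
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @return `write_split_plan()` returns `path` invisibly;
#'   `read_split_plan()` returns the `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(n = plan$n, seed = plan$seed, folds = plan$folds),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_or_len(raw$folds)), function(f) {
    fl <- if (is.data.frame(raw$folds)) raw$folds[f, ] else raw$folds[[f]]
    list(test = as.integer(unlist(fl$test)),
         validation = as.integer(unlist(fl$validation)),
         train = as.integer(unlist(fl$train)))
  })
  structure(list(folds = folds, n = as.integer(raw$n),
                 seed = as.integer(raw$seed)), class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
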
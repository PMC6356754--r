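#' Build the self-supervised training set
#'
#' Labels come for free: raw sequencer output is taken as the low-quality
#' class (label -1) and the output of any error-correction tool as the
#' high-quality class (label +1). No pairing between a corrected read and its
#' source raw read is attempted — correction tools may rename, trim or split
#' reads — so the two sets are treated as independent samples of the two
#' classes. Reads shorter than 3 bases are degenerate feature rows and are
#' excluded from training (they are still scored downstream).
#'
#' @param raw Read tibble of raw reads.
#' @param corrected Read tibble of corrected reads.
#' @return An object of class `sq_training_set`: a list with `features`
#'   (tibble: `read_id`, `source`, `label`, 84 feature columns) and counts.
#' @export
build_training_set <- function(raw, corrected) {
  if (!is.data.frame(raw) || nrow(raw) == 0L ||
      !is.data.frame(corrected) || nrow(corrected) == 0L) {
    abort("training requires both raw and corrected reads")
  }
  prep <- function(reads, source, label) {
    keep <- nchar(reads$bases) >= 3L
    if (any(!keep)) {
      inform(paste0("excluding ", sum(!keep), " ", source,
                    " read(s) shorter than 3 bases from training"))
    }
    reads <- reads[keep, , drop = FALSE]
    if (nrow(reads) == 0L) {
      abort(paste0("no ", source, " reads of length >= 3 to train on"))
    }
    dplyr::mutate(sq_features(reads), source = source, label = label,
                  .after = "read_id")
  }
  feats <- dplyr::bind_rows(
    prep(raw, "raw", -1),
    prep(corrected, "corrected", +1)
  )
  structure(
    list(features = feats,
         n_raw = sum(feats$label == -1),
         n_corrected = sum(feats$label == +1)),
    class = "sq_training_set"
  )
}

#' @export
print.sq_training_set <- function(x, ...) {
  cat("<sq_training_set> ", x$n_raw, " raw (label -1) + ", x$n_corrected,
      " corrected (label +1) reads, 84 features\n", sep = "")
  invisible(x)
}

#' Split a training set into two halves for cross-scoring
#'
#' Raw rows are randomly permuted and halved across the two parts; corrected
#' rows likewise, independently. Sizes per source differ by at most one
#' between parts; the parts partition the input exactly.
#'
#' @param ts An `sq_training_set`.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List of two `sq_training_set` objects, `part1` and `part2`.
#' @export
split_two_parts <- function(ts, seed = 0L) {
  stopifnot(inherits(ts, "sq_training_set"))
  if (ts$n_raw < 2L || ts$n_corrected < 2L) {
    abort("need at least 2 raw and 2 corrected reads to split")
  }
  feats <- ts$features
  half <- function(idx) {
    perm <- idx[sample.int(length(idx))]
    n1 <- ceiling(length(idx) / 2)
    list(perm[seq_len(n1)], perm[-seq_len(n1)])
  }
  halves <- with_seed(seed, {
    r <- half(which(feats$label == -1))
    c <- half(which(feats$label == +1))
    list(r, c)
  })
  mk <- function(i) {
    sel <- sort(c(halves[[1]][[i]], halves[[2]][[i]]))
    f <- feats[sel, , drop = FALSE]
    structure(list(features = f,
                   n_raw = sum(f$label == -1),
                   n_corrected = sum(f$label == +1)),
              class = "sq_training_set")
  }
  list(part1 = mk(1), part2 = mk(2))
}

#' Fit the linear least-squares quality scorer
#'
#' Solves `min ||Xw - Y||^2` for the 84 feature weights. Because each feature
#' order sums to one on N-free reads, `X'X` is exactly singular, so the
#' default is the minimum-norm least-squares solution (via the singular value
#' decomposition); it coincides with `(X'X)^-1 X'Y` whenever that inverse
#' exists. A ridge penalty `(X'X + ridge I)^-1 X'Y` is available as an
#' alternative. No intercept is fitted: the constant vector already lies in
#' the span of each sum-to-one feature block, and a zero feature vector
#' should score zero.
#'
#' @param ts An `sq_training_set` (or a list with a `features` tibble).
#' @param ridge Non-negative ridge penalty; 0 (default) selects the
#'   minimum-norm solution.
#' @return An object of class `sq_scorer` with elements `weights` (named
#'   numeric, length 84), `rank` (effective rank of X), `residual_norm`,
#'   `n_obs` and `ridge`.
#' @export
fit_linear <- function(ts, ridge = 0) {
  stopifnot(inherits(ts, "sq_training_set"), ridge >= 0)
  X <- feature_matrix_of(ts$features)
  Y <- ts$features$label
  if (nrow(X) == 0L) abort("empty training set")

  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < 2L) warn("feature matrix has collapsed rank; scores may be degenerate")

  if (ridge == 0) {
    # minimum-norm LS: w = V D^+ U' y
    w <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    w <- drop(w)
  } else {
    w <- drop(solve(crossprod(X) + diag(ridge, ncol(X)), crossprod(X, Y)))
  }
  names(w) <- colnames(X)
  structure(
    list(weights = w,
         rank = rank,
         residual_norm = sqrt(sum((drop(X %*% w) - Y)^2)),
         n_obs = nrow(X),
         ridge = ridge),
    class = "sq_scorer"
  )
}

#' @export
print.sq_scorer <- function(x, ...) {
  cat("<sq_scorer> 84 weights, fitted on ", x$n_obs, " reads (rank ",
      x$rank, ", ridge ", x$ridge, ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_linear
#' @param x An `sq_scorer`.
#' @param ... Unused.
#' @export
tidy.sq_scorer <- function(x, ...) {
  tibble::tibble(kmer = names(x$weights),
                 k = nchar(names(x$weights)),
                 weight = unname(x$weights))
}

#' @rdname fit_linear
#' @export
glance.sq_scorer <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, rank = x$rank,
                 residual_norm = x$residual_norm, ridge = x$ridge)
}

#' Score reads with a fitted linear scorer
#'
#' The quality score of a read is the dot product of its 84-feature content
#' vector with the fitted weights (no intercept), so scoring is linear:
#' scaling a feature vector scales its score.
#'
#' @param scorer An `sq_scorer`.
#' @param features A feature tibble from [sq_features()], an
#'   84-column matrix, or a read tibble (featurised on the fly).
#' @return If `features` carries read ids, a tibble `(read_id, sq)`;
#'   otherwise a bare numeric vector of scores.
#' @export
score_reads <- function(scorer, features) {
  stopifnot(inherits(scorer, "sq_scorer"))
  if (is.matrix(features)) {
    if (ncol(features) != 84L) {
      abort(paste0("feature matrix has ", ncol(features),
                   " columns; expected 84"))
    }
    return(drop(features %*% scorer$weights))
  }
  stopifnot(is.data.frame(features))
  if (!all(kmer_feature_names() %in% names(features))) {
    features <- sq_features(features)
  }
  X <- feature_matrix_of(features)
  tibble::tibble(read_id = features$read_id, sq = drop(X %*% scorer$weights))
}

#' Cross-score all raw reads
#'
#' The full self-supervised scoring pipeline: build the training set, split
#' it into two halves, fit a linear scorer on each half, and score each
#' half's raw reads with the model fitted on the *other* half, so that no
#' read is scored by a model that saw it during training. The two score
#' lists are pooled without rescaling. Raw reads shorter than 3 bases cannot
#' be meaningfully featurised for training and receive a sentinel `NA` score
#' that ranks below every scored read in [select_top()].
#'
#' @inheritParams build_training_set
#' @param seed Integer seed for the two-part split.
#' @param ridge Ridge penalty forwarded to [fit_linear()].
#' @return A tibble, one row per raw input read in input order, with columns
#'   `read_id`, `sq` (the quality score) and `fold` (the index, 1 or 2, of
#'   the training half whose model produced the score; `NA` for sentinel
#'   rows).
#' @export
cross_score <- function(raw, corrected, seed = 0L, ridge = 0) {
  if (anyDuplicated(raw$read_id)) {
    abort(paste0("duplicate raw read id: ",
                 raw$read_id[anyDuplicated(raw$read_id)]))
  }
  ts <- build_training_set(raw, corrected)
  parts <- split_two_parts(ts, seed = seed)
  fit1 <- fit_linear(parts$part1, ridge = ridge)
  fit2 <- fit_linear(parts$part2, ridge = ridge)

  score_half <- function(part, scorer, fold) {
    f <- part$features[part$features$label == -1, , drop = FALSE]
    X <- feature_matrix_of(f)
    tibble::tibble(read_id = f$read_id, sq = drop(X %*% scorer$weights),
                   fold = fold)
  }
  scored <- dplyr::bind_rows(
    score_half(parts$part2, fit1, 1L), # part2 scored by part1's model
    score_half(parts$part1, fit2, 2L)
  )

  m1 <- mean(scored$sq[scored$fold == 1L])
  m2 <- mean(scored$sq[scored$fold == 2L])
  s <- stats::sd(scored$sq)
  if (is.finite(s) && s > 0 && abs(m1 - m2) > 0.5 * s) {
    warn(paste0("fold score means differ by ",
                format(abs(m1 - m2) / s, digits = 3),
                " SD; the two half-models may be poorly calibrated"))
  }

  out <- tibble::tibble(read_id = raw$read_id)
  out <- dplyr::left_join(out, scored, by = "read_id")
  if (anyNA(out$sq)) {
    inform(paste0(sum(is.na(out$sq)),
                  " read(s) shorter than 3 bases received a sentinel NA ",
                  "score and will rank last"))
  }
  out
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
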
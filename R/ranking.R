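#' Construct a subjects-by-features matrix with group labels
#'
#' The contract shared by the ranking and classification stages: one row per
#' subject, one column per candidate feature, plus a two-class group label.
#'
#' @param features Numeric matrix `[n_subjects x n_features]`.
#' @param labels Character/factor vector of per-subject groups (two levels
#'   must be present, conventionally `"patient"` and `"control"`).
#' @param ids Optional data frame of per-feature metadata (one row per
#'   feature) with at least a unique `feature` column; defaults to
#'   `f1..fp`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("labels must have one entry per subject (row)")
  }
  if (length(unique(labels)) != 2L) {
    stop("feature_matrix needs exactly two classes present")
  }
  if (is.null(ids)) {
    ids <- data.frame(feature = paste0("f", seq_len(ncol(features))),
                      stringsAsFactors = FALSE)
  }
  if (nrow(ids) != ncol(features)) stop("ids must have one row per feature")
  if (anyDuplicated(ids$feature)) stop("feature ids must be unique")
  structure(list(features = features, labels = labels, ids = ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d subjects x %d features (%s)>\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a feature matrix from per-subject PAC tensors
#'
#' Flattens each subject's pair-by-segment coupling matrix (canonical
#' [band_pairs()] order, segments within pair) into one row; 7 bands and 50
#' segments give 1050 features per subject.
#'
#' @param tensors List of [pac_tensor()] objects with group labels set.
#' @return A [feature_matrix()] whose `ids` carry `lf`, `hf`, `segment` and
#'   `latency_ms` (segment centre, ms post-onset) per feature.
#' @export
pac_feature_matrix <- function(tensors) {
  stopifnot(length(tensors) >= 2L)
  ref <- tensors[[1L]]
  pairs <- band_pairs(ref$bands)
  n_seg <- ref$grid$n_segments
  feats <- t(vapply(tensors, function(t) as.vector(t(pac_matrix(t))),
                    numeric(nrow(pairs) * n_seg)))
  lat <- ref$grid$centers_ms - (ref$onset_index - 0.5) / ref$fs * 1000
  ids <- data.frame(
    lf = rep(pairs$lf, each = n_seg),
    hf = rep(pairs$hf, each = n_seg),
    segment = rep.int(seq_len(n_seg), nrow(pairs)),
    latency_ms = rep.int(lat, nrow(pairs)),
    stringsAsFactors = FALSE
  )
  ids$feature <- sprintf("%s->%s@s%02d", ids$lf, ids$hf, ids$segment)
  rownames(feats) <- vapply(tensors, `[[`, "", "subject_id")
  feature_matrix(feats, vapply(tensors, `[[`, "", "group"), ids)
}

#' Two-sample Wilcoxon rank-sum discriminability score
#'
#' The absolute value of the tie-corrected normal-approximation z statistic of
#' the two-sample rank-sum test, without continuity correction. Being
#' rank-based, the score is invariant under strictly monotone transforms of
#' the pooled values. If every pooled value is identical the score is 0.
#'
#' @param a,b Numeric samples of the two groups (each length >= 2).
#' @return Non-negative scalar.
#' @examples
#' wilcoxon_score(c(1, 2, 3), c(4, 5, 6))  # 4.5 / sqrt(5.25)
#' @export
wilcoxon_score <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  pooled <- c(a, b)
  if (!all(is.finite(pooled))) stop("wilcoxon_score() requires finite values")
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  v <- n1 * (n - n1) / (n * (n - 1)) * sum((r - (n + 1) / 2)^2)
  if (v <= 0) return(0)
  abs(w - mu) / sqrt(v)
}

# Vectorised rank-sum engine over the columns of a feature matrix.
#
# ws_engine(X, is_a) precomputes per-column sort orders and tie groups once;
# the returned function maps a vector of per-subject resampling counts to the
# |z| rank-sum score of every feature in one vectorised pass. Duplicated
# subjects (bootstrap) and cross-subject value ties both enter the variance
# through the exact tie-corrected form
#   Var(W) = n1 n2 / (N (N - 1)) * sum_k c_k (r_k - (N + 1) / 2)^2.
ws_engine <- function(X, is_a) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  O <- matrix(apply(X, 2L, order), nrow = n)       # n x p sort orders
  flat <- as.vector(O) + rep.int((seq_len(p) - 1L) * n, rep.int(n, p))
  v <- as.vector(X)[flat]                          # values, sorted per column
  newgrp <- c(TRUE, v[-1L] != v[-length(v)])
  newgrp[seq.int(1L, by = n, length.out = p)] <- TRUE
  g <- cumsum(newgrp)                              # consecutive tie groups
  grp_last <- c(which(newgrp[-1L]) , length(v))    # last obs index per group
  col_of_grp <- rep.int(seq_len(p), rep.int(n, p))[newgrp]
  a_flat <- as.vector(is_a[O])
  csum <- function(x) .colSums(x, n, p)
  function(counts) {
    c_flat <- as.vector(counts[O])
    cc <- cumsum(c_flat)
    tot_g <- diff(c(0, cc[grp_last]))
    N <- sum(counts)
    ccum <- cc[grp_last] - (col_of_grp - 1L) * N
    avgrank <- (ccum - (tot_g - 1) / 2)[g]
    ca <- c_flat * a_flat
    w <- csum(ca * avgrank)
    n1 <- csum(ca)
    s2 <- csum(c_flat * (avgrank - (N + 1) / 2)^2)
    v_w <- n1 * (N - n1) / (N * (N - 1)) * s2
    z <- abs(w - n1 * (N + 1) / 2)
    out <- numeric(p)
    ok <- v_w > 0
    out[ok] <- z[ok] / sqrt(v_w[ok])
    out
  }
}

#' Bootstrap-stabilised Wilcoxon feature ranking
#'
#' For every feature, draws `n_boot` bootstrap replicates of the cohort
#' (by default resampling subjects with replacement within each class,
#' preserving class sizes), recomputes the rank-sum score on each replicate,
#' and summarises stability as `wscore_star = boot_mean / boot_sd` (sample sd,
#' n-1 denominator) -- the inverse coefficient of variation of the score over
#' replicates. Features are ranked by `wscore_star` descending; ties break by
#' higher `boot_mean`, then canonical feature order. Features whose bootstrap
#' score never varies (`boot_sd = 0`) get `wscore_star = NA` and rank last.
#'
#' @param fm A [feature_matrix()] (both classes with >= 2 members).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param stratified Resample within class (default `TRUE`). With
#'   `stratified = FALSE` subjects are resampled from the pooled cohort and
#'   replicates that lose a class are dropped (counted and reported).
#' @return A `wscore_table`: data frame with the feature ids plus
#'   `wscore_full` (score on the unresampled cohort), `boot_mean`, `boot_sd`,
#'   `wscore_star` and `rank` (a full permutation, tie-broken as documented).
#' @export
bootstrap_wscore_star <- function(fm, n_boot = 1000, seed = 1,
                                  stratified = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- sort(unique(fm$labels))
  ia <- which(fm$labels == classes[1L])
  ib <- which(fm$labels == classes[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both classes need >= 2 members")
  }
  n <- nrow(fm$features)
  p <- ncol(fm$features)
  engine <- ws_engine(fm$features, as.numeric(fm$labels == classes[1L]))
  full <- engine(rep(1, n))
  s1 <- numeric(p)
  s2 <- numeric(p)
  n_used <- 0L
  n_dropped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      if (stratified) {
        draw <- c(sample(ia, length(ia), replace = TRUE),
                  sample(ib, length(ib), replace = TRUE))
      } else {
        draw <- sample(n, n, replace = TRUE)
        if (!any(draw %in% ia) || !any(draw %in% ib)) {
          n_dropped <- n_dropped + 1L
          next
        }
      }
      sc <- engine(tabulate(draw, nbins = n))
      s1 <- s1 + sc
      s2 <- s2 + sc * sc
      n_used <- n_used + 1L
    }
  })
  if (n_dropped > 0L) {
    message(sprintf("bootstrap_wscore_star: dropped %d one-class replicate(s)",
                    n_dropped))
  }
  if (n_used < 2L) stop("fewer than 2 usable bootstrap replicates")
  boot_mean <- s1 / n_used
  boot_var <- pmax(0, (s2 - n_used * boot_mean^2) / (n_used - 1))
  boot_sd <- sqrt(boot_var)
  star <- ifelse(boot_sd > 0, boot_mean / boot_sd, NA_real_)
  ord <- order(-ifelse(is.na(star), -Inf, star), -boot_mean, seq_len(p))
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  tab <- cbind(
    fm$ids,
    data.frame(wscore_full = full, boot_mean = boot_mean, boot_sd = boot_sd,
               wscore_star = star, rank = rk)
  )
  attr(tab, "n_boot") <- n_used
  attr(tab, "seed") <- seed
  attr(tab, "stratified") <- stratified
  class(tab) <- c("wscore_table", "data.frame")
  tab
}

#' Select the top-ranked features
#'
#' @param table A `wscore_table` from [bootstrap_wscore_star()].
#' @param p Number of features to keep (default 30).
#' @return Integer vector of feature column indices in rank order (rank 1
#'   first), with the feature ids as names.
#' @export
select_top <- function(table, p = 30) {
  stopifnot(inherits(table, "wscore_table"))
  if (p > nrow(table)) {
    stop(sprintf("requested top %d of only %d features", p, nrow(table)))
  }
  idx <- order(table$rank)[seq_len(p)]
  stats::setNames(idx, table$feature[idx])
}

#' Cross-validated accuracy as a function of feature-count p
#'
#' Runs the classification stage at each candidate dimensionality and returns
#' the accuracy curve, used to justify the default `p`.
#'
#' @param fm A [feature_matrix()].
#' @param p_values Integer vector of feature counts to evaluate.
#' @param scheme `"loocv"` (default) or `"repeated_split"`.
#' @param mode Feature-selection protocol, see [loocv()] (default
#'   `"paper_faithful"`, which selects once per curve point on the full
#'   cohort -- appropriate for a tuning curve, not for unbiased accuracy).
#' @param n_boot,seed Passed to the ranking stage.
#' @param ... Further arguments for [loocv()] / [repeated_split()].
#' @return Data frame with columns `p` and `accuracy`.
#' @export
sweep_p <- function(fm, p_values, scheme = c("loocv", "repeated_split"),
                    mode = "paper_faithful", n_boot = 200, seed = 1, ...) {
  scheme <- match.arg(scheme)
  stopifnot(all(p_values >= 1), all(p_values <= ncol(fm$features)))
  acc <- vapply(p_values, function(p) {
    res <- if (scheme == "loocv") {
      loocv(fm, p = p, mode = mode, n_boot = n_boot, seed = seed, ...)
    } else {
      repeated_split(fm, p = p, mode = mode, n_boot = n_boot, seed = seed, ...)
    }
    res$accuracy
  }, numeric(1L))
  data.frame(p = p_values, accuracy = acc)
}
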
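# Plain-text serialization: every artifact is a TSV of full-precision numbers
# plus a JSON sidecar carrying metadata and a schema tag. Loaders validate the
# schema tag and the object invariants rather than trusting the files.

SCHEMA <- list(trial_set = "tvpac/trial_set/1",
               pac_tensor = "tvpac/pac_tensor/1",
               wscore_table = "tvpac/wscore_table/1",
               feature_matrix = "tvpac/feature_matrix/1",
               cv_result = "tvpac/cv_result/1")

write_num_tsv <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_num_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

read_meta <- function(path, what) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA[[what]])) {
    stop(sprintf("schema mismatch in %s: expected %s, found %s",
                 path, SCHEMA[[what]],
                 if (is.null(meta$schema)) "<none>" else meta$schema))
  }
  meta
}

write_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Write / read a trial set
#'
#' `write_trialset()` stores the trials-by-samples matrix as `<prefix>.tsv`
#' and the metadata (subject, group, condition, fs, onset) as
#' `<prefix>.json`; `read_trialset()` loads and re-validates it.
#'
#' @param ts A [trial_set()].
#' @param prefix File path prefix (without extension).
#' @return `write_trialset()` the prefix, invisibly; `read_trialset()` the
#'   `trial_set`.
#' @export
write_trialset <- function(ts, prefix) {
  stopifnot(inherits(ts, "trial_set"))
  write_num_tsv(ts$data, paste0(prefix, ".tsv"))
  write_meta(list(schema = SCHEMA$trial_set, subject_id = ts$subject_id,
                  group = ts$group, condition = ts$condition, fs = ts$fs,
                  onset_index = ts$onset_index,
                  n_trials = nrow(ts$data), n_samples = ncol(ts$data)),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(prefix) {
  meta <- read_meta(paste0(prefix, ".json"), "trial_set")
  dat <- read_num_tsv(paste0(prefix, ".tsv"))
  if (!identical(dim(dat), c(meta$n_trials, meta$n_samples))) {
    stop("trial set data shape disagrees with its header")
  }
  trial_set(dat, meta$fs, subject_id = meta$subject_id, group = meta$group,
            condition = meta$condition, onset_index = meta$onset_index)
}

#' Write / read a PAC tensor
#'
#' The pair-by-segment values go to `<prefix>.tsv` (canonical pair order); the
#' bands, grid and subject metadata to `<prefix>.json`. `pac_tensor_long()`
#' gives a long-format export (subject, lf, hf, segment, center_ms, plv).
#'
#' @param tensor A [pac_tensor()].
#' @param prefix File path prefix.
#' @return `write_pac_tensor()` the prefix, invisibly; `read_pac_tensor()` the
#'   tensor.
#' @export
write_pac_tensor <- function(tensor, prefix) {
  stopifnot(inherits(tensor, "pac_tensor"))
  write_num_tsv(pac_matrix(tensor), paste0(prefix, ".tsv"))
  bands <- lapply(tensor$bands, function(b) {
    list(name = b$name, f_low = b$f_low, f_high = b$f_high)
  })
  write_meta(list(schema = SCHEMA$pac_tensor, subject_id = tensor$subject_id,
                  group = tensor$group, condition = tensor$condition,
                  fs = tensor$fs, onset_index = tensor$onset_index,
                  step_ms = tensor$grid$step_ms,
                  n_samples = tensor$grid$end[length(tensor$grid$end)],
                  bands = bands),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_pac_tensor
#' @export
read_pac_tensor <- function(prefix) {
  meta <- read_meta(paste0(prefix, ".json"), "pac_tensor")
  m <- read_num_tsv(paste0(prefix, ".tsv"))
  bands <- lapply(seq_len(nrow(meta$bands)), function(k) {
    band_spec(meta$bands$name[k], meta$bands$f_low[k], meta$bands$f_high[k])
  })
  grid <- segment_grid(meta$n_samples, meta$fs, meta$step_ms)
  pairs <- band_pairs(bands)
  if (nrow(m) != nrow(pairs) || ncol(m) != grid$n_segments) {
    stop("PAC tensor data shape disagrees with its header")
  }
  nb <- length(bands)
  vals <- array(0, dim = c(nb, nb, grid$n_segments))
  for (k in seq_len(nrow(pairs))) vals[pairs$i[k], pairs$j[k], ] <- m[k, ]
  nms <- vapply(bands, `[[`, "", "name")
  dimnames(vals) <- list(nms, nms, NULL)
  structure(
    list(values = vals, bands = bands, grid = grid,
         subject_id = meta$subject_id, group = meta$group,
         condition = meta$condition, onset_index = meta$onset_index,
         fs = meta$fs),
    class = "pac_tensor"
  )
}

#' @rdname write_pac_tensor
#' @export
pac_tensor_long <- function(tensor) {
  stopifnot(inherits(tensor, "pac_tensor"))
  pairs <- band_pairs(tensor$bands)
  n_seg <- tensor$grid$n_segments
  m <- pac_matrix(tensor)
  data.frame(
    subject = tensor$subject_id,
    lf = rep(pairs$lf, each = n_seg),
    hf = rep(pairs$hf, each = n_seg),
    segment = rep.int(seq_len(n_seg), nrow(pairs)),
    center_ms = rep.int(tensor$grid$centers_ms, nrow(pairs)),
    plv = as.vector(t(m)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a ranking table
#'
#' @param table A `wscore_table` from [bootstrap_wscore_star()].
#' @param prefix File path prefix.
#' @return The prefix / the table.
#' @export
write_wscore_table <- function(table, prefix) {
  stopifnot(inherits(table, "wscore_table"))
  utils::write.table(
    format(as.data.frame(table), digits = 17, trim = TRUE),
    paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  write_meta(list(schema = SCHEMA$wscore_table,
                  n_boot = attr(table, "n_boot"),
                  seed = attr(table, "seed"),
                  stratified = attr(table, "stratified"),
                  columns = names(table)),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_wscore_table
#' @export
read_wscore_table <- function(prefix) {
  meta <- read_meta(paste0(prefix, ".json"), "wscore_table")
  tab <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  names(tab) <- meta$columns
  attr(tab, "n_boot") <- meta$n_boot
  attr(tab, "seed") <- meta$seed
  attr(tab, "stratified") <- meta$stratified
  class(tab) <- c("wscore_table", "data.frame")
  tab
}

#' Write / read a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param prefix File path prefix.
#' @return The prefix / the feature matrix.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  write_num_tsv(fm$features, paste0(prefix, ".tsv"))
  write_meta(list(schema = SCHEMA$feature_matrix, labels = fm$labels,
                  subjects = rownames(fm$features), ids = fm$ids),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  meta <- read_meta(paste0(prefix, ".json"), "feature_matrix")
  feats <- read_num_tsv(paste0(prefix, ".tsv"))
  if (!is.null(meta$subjects)) rownames(feats) <- meta$subjects
  feature_matrix(feats, meta$labels, as.data.frame(meta$ids))
}

#' Write / read a cross-validation result
#'
#' @param res A `cv_result` from [loocv()] or [repeated_split()].
#' @param path JSON file path.
#' @return The path / the result.
#' @export
write_cv_result <- function(res, path) {
  stopifnot(inherits(res, "cv_result"))
  payload <- unclass(res)
  payload$schema <- SCHEMA$cv_result
  write_meta(payload, path)
  invisible(path)
}

#' @rdname write_cv_result
#' @export
read_cv_result <- function(path) {
  meta <- read_meta(path, "cv_result")
  meta$schema <- NULL
  if (!is.null(meta$per_fold) && is.data.frame(meta$per_fold)) {
    meta$per_fold <- lapply(seq_len(nrow(meta$per_fold)), function(k) {
      as.list(meta$per_fold[k, ])
    })
  }
  structure(meta, class = "cv_result")
}
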
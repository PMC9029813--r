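#' Construct a fingerprint dataset
#'
#' The central data container: one row per molecule, one column per
#' fingerprint feature. Raw extended-connectivity count fingerprints hold
#' non-negative integer counts; scaled variants (after [minmax_scale()])
#' or autoencoder codes hold reals in \[0, 1\].
#'
#' @param ids Character vector of unique molecule identifiers.
#' @param labels Character vector of activity-class labels, one per
#'   molecule. The reserved label `"__bg__"` (see [background_label()])
#'   marks inactive/background molecules.
#' @param counts Numeric matrix, molecules x features, entries >= 0.
#'   Must be integer-valued unless `scaled = TRUE`.
#' @param scaled Logical; `TRUE` when entries are min-max scaled reals.
#' @param scaling Optional list with per-feature `min` and `max` vectors
#'   recorded by [minmax_scale()]; required to invert the scaling.
#' @return An object of class `fingerprint_dataset`.
#' @export
#' @examples
#' ds <- fingerprint_dataset(
#'   ids = c("m1", "m2"), labels = c("A", "A"),
#'   counts = matrix(c(0, 2, 1, 0, 3, 1), nrow = 2)
#' )
#' ds
fingerprint_dataset <- function(ids, labels, counts, scaled = FALSE,
                                scaling = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (anyDuplicated(ids)) {
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) != nrow(counts) || length(labels) != nrow(counts)) {
    stop("ids, labels and rows of counts must have equal length")
  }
  if (nrow(counts) > 0 && ncol(counts) > 0) {
    if (anyNA(counts)) stop("counts contain missing values")
    if (min(counts) < 0) {
      bad <- which(counts < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at row %d, column %d", bad[1], bad[2]))
    }
    if (!scaled && any(counts != floor(counts))) {
      bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count at row %d, column %d in unscaled data",
                   bad[1], bad[2]))
    }
  }
  if (!is.null(scaling)) {
    stopifnot(length(scaling$min) == ncol(counts),
              length(scaling$max) == ncol(counts),
              all(scaling$max >= scaling$min))
  }
  if (is.null(colnames(counts))) colnames(counts) <- feature_names(ncol(counts))
  rownames(counts) <- ids
  structure(
    list(ids = ids, labels = labels, counts = counts,
         feature_dim = ncol(counts), scaled = isTRUE(scaled),
         scaling = scaling),
    class = "fingerprint_dataset"
  )
}

feature_names <- function(f) {
  if (f == 0) return(character(0))
  sprintf(paste0("f%0", max(4, nchar(f - 1)), "d"), seq_len(f) - 1)
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  nc <- length(unique(x$labels[x$labels != BG_LABEL]))
  cat(sprintf(
    "<fingerprint_dataset> %d molecules x %d features (%s), %d activity class%s, %d background\n",
    length(x$ids), x$feature_dim, if (x$scaled) "scaled" else "integer counts",
    nc, if (nc == 1) "" else "es", sum(x$labels == BG_LABEL)))
  invisible(x)
}

#' @export
dim.fingerprint_dataset <- function(x) dim(x$counts)

#' Read a fingerprint dataset from CSV
#'
#' Expects the column layout written by [write_fingerprints()]: an `id`
#' column, an `activity` column, then one column per feature
#' (`f0000`..`f1023` for the default 1024-feature fingerprints).
#'
#' @param path Path to a CSV file.
#' @param scaled Logical; set `TRUE` when the file stores scaled reals
#'   rather than integer counts.
#' @return A [fingerprint_dataset()]. Row order is preserved.
#' @export
read_fingerprints <- function(path, scaled = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!all(c("id", "activity") %in% hdr)) {
    stop("header must name 'id' and 'activity' columns")
  }
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(id = "character", activity = "character"))
  feat <- setdiff(names(df), c("id", "activity"))
  counts <- as.matrix(df[, feat, drop = FALSE])
  if (nrow(counts) == 0) {
    counts <- matrix(numeric(0), 0, length(feat),
                     dimnames = list(NULL, feat))
  }
  if (!is.numeric(counts)) {
    bad <- which(!vapply(df[, feat, drop = FALSE], is.numeric, logical(1)))[1]
    stop("non-numeric counts in column ", feat[bad])
  }
  fingerprint_dataset(df$id, df$activity, counts, scaled = scaled)
}

#' Write a fingerprint dataset to CSV
#'
#' Integer datasets round-trip bit-exactly through [read_fingerprints()];
#' scaled datasets are written with full double precision (17 significant
#' digits).
#'
#' @param ds A [fingerprint_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(ds, path) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  vals <- if (ds$scaled) {
    apply(ds$counts, 2, function(col) sprintf("%.17g", col))
  } else {
    apply(ds$counts, 2, function(col) sprintf("%d", as.integer(col)))
  }
  if (length(ds$ids) == 1) vals <- matrix(vals, nrow = 1)
  df <- data.frame(id = ds$ids, activity = ds$labels, check.names = FALSE)
  if (length(ds$ids) == 0) {
    # header-only file for the empty dataset
    cat(paste(c("id", "activity", colnames(ds$counts)), collapse = ","),
        "\n", sep = "", file = path)
    return(invisible(path))
  }
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  names(df) <- c("id", "activity", colnames(ds$counts))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max scale fingerprint features to \[0, 1\]
#'
#' Maps each feature through `(x - min) / (max - min)` so the data lie in
#' the output range of the autoencoder's sigmoid layers. Constant
#' features map to 0. The per-feature minima and maxima are stored on the
#' result so [inverse_scale()] can recover the original counts.
#'
#' @param ds An unscaled [fingerprint_dataset()].
#' @return A scaled `fingerprint_dataset` carrying its scaling parameters.
#' @export
#' @seealso [inverse_scale()], [binarize()]
minmax_scale <- function(ds) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  if (ds$scaled) stop("dataset is already scaled")
  mins <- apply(ds$counts, 2, min)
  maxs <- apply(ds$counts, 2, max)
  rng <- maxs - mins
  scaled <- sweep(ds$counts, 2, mins, "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  fingerprint_dataset(ds$ids, ds$labels, scaled, scaled = TRUE,
                      scaling = list(min = mins, max = maxs))
}

#' Invert a min-max scaling
#'
#' @param ds A scaled [fingerprint_dataset()] carrying scaling parameters.
#' @return The unscaled dataset (constant features are restored from the
#'   recorded minima).
#' @export
inverse_scale <- function(ds) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  if (!ds$scaled || is.null(ds$scaling)) {
    stop("dataset is not scaled or has no scaling parameters")
  }
  rng <- ds$scaling$max - ds$scaling$min
  raw <- sweep(ds$counts, 2, rng, "*")
  raw <- sweep(raw, 2, ds$scaling$min, "+")
  raw <- round(raw, 9)  # kill 1e-16 noise so integer validation passes
  fingerprint_dataset(ds$ids, ds$labels, raw, scaled = FALSE)
}

#' Binarize count fingerprints
#'
#' Entry becomes 1 wherever the count is positive — the presence/absence
#' form used by the binary Tanimoto baseline. Idempotent.
#'
#' @param ds An unscaled [fingerprint_dataset()].
#' @return A `fingerprint_dataset` with entries in {0, 1}.
#' @export
binarize <- function(ds) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  if (ds$scaled) stop("binarize expects unscaled count data")
  fingerprint_dataset(ds$ids, ds$labels, (ds$counts > 0) * 1)
}

#' Mean intra-class pairwise similarity
#'
#' Measures how structurally homogeneous an activity class is: the mean
#' Tanimoto similarity over all unordered pairs of class members. The
#' conventional form matches every structure against every other in its
#' class using the binary Tanimoto coefficient on binarized fingerprints;
#' `variant = "continuous"` uses the continuous coefficient on the raw
#' counts instead.
#'
#' @param ds A [fingerprint_dataset()] (unscaled counts).
#' @param label An activity-class label present in `ds` with >= 2 members.
#' @param variant `"binary"` (default) or `"continuous"`.
#' @return Mean pairwise similarity in \[0, 1\].
#' @export
#' @examples
#' ds <- fingerprint_dataset(c("a", "b"), c("A", "A"),
#'                           matrix(c(1, 1, 2, 2, 0, 0), nrow = 2))
#' class_diversity(ds, "A")  # identical rows -> 1
class_diversity <- function(ds, label, variant = c("binary", "continuous")) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  variant <- match.arg(variant)
  idx <- which(ds$labels == label)
  if (length(idx) == 0) stop("unknown activity class: ", label)
  if (length(idx) < 2) stop("class '", label, "' has fewer than 2 members")
  x <- ds$counts[idx, , drop = FALSE]
  if (variant == "binary") x <- (x > 0) * 1
  # Gram-matrix form: all pairwise <a,b>, |a|^2, |b|^2 at once
  g <- tcrossprod(x)
  sq <- diag(g)
  denom <- outer(sq, sq, "+") - g
  sim <- ifelse(denom > 0, g / denom, 1)  # two all-zero rows: identical
  ut <- upper.tri(sim)
  mean(sim[ut])
}
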
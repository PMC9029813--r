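#' Screening protocol configuration
#'
#' The simulated virtual-screening protocol: a number of reference
#' structures are drawn at random from each activity class, the database
#' is ranked by similarity to each reference in decreasing order, and
#' the percentage of the class's actives retrieved within the top-p%
#' cutoffs is averaged over the references.
#'
#' @param n_references References sampled per class (default 10).
#' @param cutoffs Percentage cutoffs, each in (0, 100\] (default
#'   `c(1, 5)`).
#' @param seed Integer seed for reference selection.
#' @param exclude_reference Logical; drop the reference molecule from
#'   both the ranked database and the active count (default `TRUE`,
#'   avoiding a guaranteed self-hit).
#' @param variant Similarity variant: `"standard"`, `"as_printed"` or
#'   `"binary"` (see [similarity_scores()]).
#' @return A `screening_config` list.
#' @export
screening_config <- function(n_references = 10, cutoffs = c(1, 5), seed = 1,
                             exclude_reference = TRUE,
                             variant = c("standard", "as_printed", "binary")) {
  variant <- match.arg(variant)
  stopifnot(n_references >= 1, all(cutoffs > 0), all(cutoffs <= 100))
  structure(list(n_references = as.integer(n_references), cutoffs = cutoffs,
                 seed = as.integer(seed),
                 exclude_reference = isTRUE(exclude_reference),
                 variant = variant),
            class = "screening_config")
}

#' Select reference structures from a class
#'
#' Samples `n_references` molecule ids without replacement from the
#' class, deterministically for a given seed (and label). Classes
#' smaller than `n_references` contribute all their members, with a
#' warning.
#'
#' @param ds A [fingerprint_dataset()].
#' @param label Activity-class label.
#' @param cfg A [screening_config()].
#' @return Character vector of molecule ids.
#' @export
select_references <- function(ds, label, cfg = screening_config()) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  members <- ds$ids[ds$labels == label]
  if (length(members) == 0) stop("unknown activity class: ", label)
  if (length(members) <= cfg$n_references) {
    if (length(members) < cfg$n_references) {
      warning(sprintf("class '%s' has %d members < %d references; using all",
                      label, length(members), cfg$n_references))
    }
    return(members)
  }
  set.seed(derive_seed(cfg$seed, paste0("refs:", label)))
  sample(members, cfg$n_references)
}

#' Rank the database against a query molecule
#'
#' Scores every database molecule against the query with the configured
#' similarity variant and sorts in decreasing score order; ties are
#' broken by molecule id ascending so rankings are reproducible.
#'
#' @param query_id Id of the query (reference) molecule in `ds`.
#' @param ds The database as a [fingerprint_dataset()].
#' @param cfg A [screening_config()]; `exclude_reference` controls
#'   whether the query itself appears in the ranking.
#' @return Data frame with columns `id` and `score`, best first.
#' @export
rank_database <- function(query_id, ds, cfg = screening_config()) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  qi <- match(query_id, ds$ids)
  if (is.na(qi)) stop("unknown query id: ", query_id)
  keep <- if (cfg$exclude_reference) setdiff(seq_along(ds$ids), qi)
          else seq_along(ds$ids)
  scores <- similarity_scores(ds$counts[qi, ], ds$counts[keep, , drop = FALSE],
                              variant = cfg$variant)
  ids <- ds$ids[keep]
  ord <- order(-scores, ids, method = "radix")
  data.frame(id = ids[ord], score = scores[ord])
}

#' Recall within a top-percentage cutoff
#'
#' The cutoff depth is `k = round(cutoff * db_size / 100)`, never less
#' than 1; recall is the percentage of the actives found among the top
#' `k` ranked molecules.
#'
#' @param ranked Character vector of ranked ids, best first; its length
#'   must equal `db_size`.
#' @param actives Character vector (or set) of active molecule ids.
#' @param cutoff Percentage in (0, 100\].
#' @param db_size Number of molecules in the ranked database.
#' @return Recall percentage in \[0, 100\].
#' @export
#' @examples
#' recall_at_cutoff(as.character(1:10), actives = c("1", "7", "20"),
#'                  cutoff = 50, db_size = 10)
recall_at_cutoff <- function(ranked, actives, cutoff, db_size = length(ranked)) {
  if (length(actives) == 0) stop("actives must be nonempty")
  if (length(ranked) != db_size) stop("ranked length must equal db_size")
  k <- max(1L, as.integer(round(cutoff * db_size / 100)))
  100 * length(intersect(head(ranked, k), actives)) / length(actives)
}

#' Screen one activity class
#'
#' For each sampled reference: rank the database, compute the recall of
#' the class's remaining actives at each cutoff, then average over the
#' references.
#'
#' @param ds Database as a [fingerprint_dataset()].
#' @param label Activity class to screen.
#' @param cfg A [screening_config()].
#' @param references Optional explicit reference ids (defaults to
#'   [select_references()]).
#' @return Named numeric vector of mean recalls, one per cutoff (names
#'   like `"1%"`).
#' @export
screen_class <- function(ds, label, cfg = screening_config(),
                         references = NULL) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  if (label == BG_LABEL) stop("background molecules form no activity class")
  members <- ds$ids[ds$labels == label]
  if (length(members) == 0) stop("unknown activity class: ", label)
  refs <- references %||% select_references(ds, label, cfg)
  per_ref <- vapply(refs, function(r) {
    ranked <- rank_database(r, ds, cfg)
    actives <- if (cfg$exclude_reference) setdiff(members, r) else members
    vapply(cfg$cutoffs, function(p) {
      recall_at_cutoff(ranked$id, actives, p, nrow(ranked))
    }, numeric(1))
  }, numeric(length(cfg$cutoffs)))
  out <- rowMeans(matrix(per_ref, nrow = length(cfg$cutoffs)))
  names(out) <- paste0(cfg$cutoffs, "%")
  out
}

#' Recall table (classes x methods)
#'
#' One row per activity class, one column per screening method; each
#' cell is the class's mean recall percentage at the stated cutoff. The
#' summary rows — per-method mean over classes and the count of classes
#' where each method achieves the row maximum (ties credit every tied
#' method) — are always recomputed from the cells.
#'
#' @param recalls Numeric matrix with class labels as rownames and
#'   method names as colnames, entries in \[0, 100\].
#' @param cutoff The percentage cutoff the table refers to.
#' @return A `recall_table` object with elements `recalls`, `cutoff`,
#'   `mean_row` and `best_counts`.
#' @export
recall_table <- function(recalls, cutoff = NA_real_) {
  recalls <- as.matrix(recalls)
  stopifnot(nrow(recalls) >= 1, ncol(recalls) >= 1,
            all(recalls >= 0), all(recalls <= 100))
  if (is.null(rownames(recalls)) || is.null(colnames(recalls))) {
    stop("recalls must carry class rownames and method colnames")
  }
  s <- compute_summary(recalls)
  structure(list(recalls = recalls, cutoff = cutoff,
                 mean_row = s$mean_row, best_counts = s$best_counts),
            class = "recall_table")
}

compute_summary <- function(recalls) {
  mean_row <- colMeans(recalls)
  row_max <- apply(recalls, 1, max)
  best_counts <- colSums(recalls == row_max)
  list(mean_row = mean_row, best_counts = best_counts)
}

#' Summary rows of a recall table
#'
#' @param table A [recall_table()] or a plain classes x methods matrix.
#' @return List with `mean_row` (per-method mean recall over classes)
#'   and `best_counts` (classes where the method attains the row
#'   maximum; ties credit all tied methods).
#' @export
#' @examples
#' m <- matrix(c(10, 30, 20, 30), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("A", "B")))
#' summarize_table(m)
summarize_table <- function(table) {
  if (inherits(table, "recall_table")) table <- table$recalls
  compute_summary(as.matrix(table))
}

#' @export
print.recall_table <- function(x, ...) {
  cat(sprintf("<recall_table> %d classes x %d methods, cutoff %s%%\n",
              nrow(x$recalls), ncol(x$recalls),
              format(x$cutoff)))
  m <- rbind(x$recalls, Mean = x$mean_row, Best = x$best_counts)
  print(round(m, 2))
  invisible(x)
}

#' Run the full screening benchmark
#'
#' Screens every activity class with every method and assembles one
#' recall table per cutoff. Methods are alternative representations of
#' the same molecules — e.g. the raw binarized fingerprints under binary
#' Tanimoto as the TAN baseline, and each autoencoder code set under
#' continuous Tanimoto — so all method datasets must share ids and
#' labels.
#'
#' @param methods Named list; each element is a list with `dataset` (a
#'   [fingerprint_dataset()]) and optionally `variant` (defaults to the
#'   config's variant).
#' @param cfg A [screening_config()]. Reference selection is shared
#'   across methods (same ids for every column, as in a unified
#'   benchmark).
#' @return Named list of [recall_table()]s, one per cutoff.
#' @export
run_benchmark <- function(methods, cfg = screening_config()) {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  ref_ds <- methods[[1]]$dataset
  for (m in methods) {
    if (!identical(m$dataset$ids, ref_ds$ids) ||
        !identical(m$dataset$labels, ref_ds$labels)) {
      stop("method datasets must share ids and labels")
    }
  }
  classes <- setdiff(unique(ref_ds$labels), BG_LABEL)
  refs <- lapply(classes, function(cl) select_references(ref_ds, cl, cfg))
  names(refs) <- classes
  cells <- lapply(names(methods), function(name) {
    m <- methods[[name]]
    mcfg <- cfg
    mcfg$variant <- m$variant %||% cfg$variant
    res <- vapply(classes, function(cl) {
      screen_class(m$dataset, cl, mcfg, references = refs[[cl]])
    }, numeric(length(cfg$cutoffs)))
    t(matrix(res, nrow = length(cfg$cutoffs)))  # classes x cutoffs
  })
  out <- lapply(seq_along(cfg$cutoffs), function(ci) {
    recalls <- vapply(cells, function(x) x[, ci], numeric(length(classes)))
    recalls <- matrix(recalls, nrow = length(classes),
                      dimnames = list(classes, names(methods)))
    recall_table(recalls, cutoff = cfg$cutoffs[ci])
  })
  names(out) <- paste0(cfg$cutoffs, "%")
  out
}

#' Read / write recall tables as CSV
#'
#' Layout: a `class` column followed by one column per method. Any
#' `Mean` or best-count summary rows present in the file are dropped and
#' recomputed — summaries are never trusted from input.
#'
#' @param path CSV file path.
#' @param cutoff Cutoff percentage to record on the table (optional).
#' @return A [recall_table()].
#' @export
read_recall_table <- function(path, cutoff = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = c(class = "character"))
  if (!"class" %in% names(df)) stop("header must name a 'class' column")
  drop <- tolower(df$class) %in% c("mean", "best", "shaded cells", "shaded_cells")
  df <- df[!drop, , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "class"), drop = FALSE])
  rownames(m) <- df$class
  recall_table(m, cutoff = cutoff)
}

#' @rdname read_recall_table
#' @param table A [recall_table()] to write.
#' @export
write_recall_table <- function(table, path) {
  stopifnot(inherits(table, "recall_table"))
  df <- data.frame(class = rownames(table$recalls), table$recalls,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled MDDR benchmark recall tables
#'
#' Per-class mean recall percentages of six screening methods (TAN,
#' ASMTP, SQB and the three autoencoder descriptors AE1/AE2/AE3-DR) on
#' the MDDR DS1/DS2/DS3 activity-class benchmarks at the top-1% and
#' top-5% cutoffs, as published. DS3 has no ASMTP column. These tables
#' are evaluation inputs: the package recomputes their summary
#' statistics and concordance analysis but cannot regenerate the cells
#' themselves, which require the licensed MDDR data.
#'
#' @param dataset `"ds1"`, `"ds2"` or `"ds3"`.
#' @param cutoff 1 or 5.
#' @return A [recall_table()].
#' @export
#' @examples
#' t4 <- benchmark_recall_table("ds1", 1)
#' summarize_table(t4)$mean_row
benchmark_recall_table <- function(dataset = c("ds1", "ds2", "ds3"),
                                   cutoff = 1) {
  dataset <- match.arg(dataset)
  stopifnot(cutoff %in% c(1, 5))
  f <- system.file("extdata",
                   sprintf("recall_%s_top%d.csv", dataset, cutoff),
                   package = "aescreen", mustWork = TRUE)
  read_recall_table(f, cutoff = cutoff)
}
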
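#' DEL tag-count table
#'
#' The central object of a DEL screen: per-compound, per-condition integer
#' sequence counts, keyed by the building-block tuple. Condition totals may
#' exceed the mapped column sums (unmapped reads are kept in an explicit
#' per-condition bucket, never dropped silently) and are the CPM
#' denominators.
#'
#' @param bb data.frame of per-position building-block ids (columns
#'   \code{pos1}, \code{pos2}, ...), one row per compound.
#' @param counts integer matrix, rows matching \code{bb}, one named column
#'   per condition.
#' @param totals named total reads per condition; default mapped + unmapped.
#' @param unmapped named unmapped read counts per condition; default 0.
#' @return object of class \code{count_table}.
#' @export
count_table <- function(bb, counts, totals = NULL, unmapped = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(nrow(bb) == nrow(counts), !is.null(colnames(counts)),
            all(counts >= 0))
  id <- compound_ids(bb)
  if (anyDuplicated(id)) stop("duplicate compound rows in count table")
  conds <- colnames(counts)
  if (is.null(unmapped)) unmapped <- stats::setNames(rep(0L, length(conds)), conds)
  unmapped <- unmapped[conds]
  if (is.null(totals)) totals <- colSums(counts) + unmapped
  totals <- totals[conds]
  if (any(totals < colSums(counts) + unmapped))
    stop("condition totals smaller than column sums")
  structure(list(bb = bb, counts = counts, compound_id = id,
                 conditions = conds, totals = totals, unmapped = unmapped),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("DEL count table: %s compounds x %d conditions (%s)\n",
              format(nrow(x$counts), big.mark = ","),
              length(x$conditions), paste(x$conditions, collapse = ", ")))
  cat("  totals:", paste(sprintf("%s=%g", x$conditions, x$totals),
                         collapse = ", "), "\n")
  if (any(x$unmapped > 0))
    cat("  unmapped:", paste(sprintf("%s=%g", x$conditions, x$unmapped),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Write / read the count-table TSV dialect
#'
#' Columns: one per position (\code{pos1}, ...), then one integer count
#' column per condition; header row. Unmapped reads are written as a single
#' row with \code{"*"} in every position column.
#'
#' @param x a \code{\link{count_table}}.
#' @param path file path.
#' @return \code{write_count_table}: \code{path}, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- cbind(x$bb, as.data.frame(x$counts))
  if (any(x$unmapped > 0)) {
    um <- c(as.list(stats::setNames(rep("*", ncol(x$bb)), names(x$bb))),
            as.list(x$unmapped))
    df <- rbind(df, as.data.frame(um, col.names = names(df)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @return \code{read_count_table}: a \code{\link{count_table}}.
#' @export
read_count_table <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed count TSV: ", conditionMessage(e)))
  pos_cols <- grep("^pos[0-9]+$", names(df), value = TRUE)
  if (!length(pos_cols)) stop("no position columns (pos1, pos2, ...) in ", path)
  cond_cols <- setdiff(names(df), pos_cols)
  if (!length(cond_cols)) stop("no condition count columns in ", path)
  for (cc in cond_cols) {
    z <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(z) | z != floor(z) | z < 0)
    if (length(bad))
      stop(sprintf("malformed count in column '%s', line %d", cc, bad[1] + 1L))
  }
  is_um <- Reduce(`&`, lapply(df[pos_cols], function(v) v == "*"))
  um_rows <- df[is_um, cond_cols, drop = FALSE]
  unmapped <- stats::setNames(
    if (nrow(um_rows)) as.integer(colSums(um_rows)) else rep(0L, length(cond_cols)),
    cond_cols)
  df <- df[!is_um, , drop = FALSE]
  bb <- df[pos_cols]
  counts <- as.matrix(df[cond_cols])
  rownames(bb) <- NULL
  dimnames(counts) <- list(NULL, cond_cols)
  count_table(bb = bb, counts = counts, unmapped = unmapped)
}

#' Tally decoded tag reads against a library
#'
#' Each read is a compound id (position-wise building-block ids joined with
#' \code{"|"}). Reads whose tag does not map to a library compound are
#' counted in the unmapped bucket.
#'
#' @param tag_reads character vector of compound-id reads, or a named list
#'   of such vectors (one element per condition).
#' @param library a \code{\link{gen_library}} result.
#' @return a \code{\link{count_table}}.
#' @export
decode_tags <- function(tag_reads, library) {
  stopifnot(inherits(library, "del_library"))
  if (!is.list(tag_reads)) tag_reads <- list(reads = tag_reads)
  if (is.null(names(tag_reads))) stop("tag read sets must be named")
  n <- length(library$compound_id)
  counts <- sapply(tag_reads, function(reads) {
    idx <- match(reads, library$compound_id)
    tabulate(idx[!is.na(idx)], nbins = n)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = n)
  colnames(counts) <- names(tag_reads)
  unmapped <- vapply(tag_reads, function(reads)
    sum(is.na(match(reads, library$compound_id))), integer(1))
  count_table(bb = library$bb, counts = counts, unmapped = unmapped)
}

#' Remove compounds observed with fewer than k sequence counts
#'
#' A compound is retained when its maximum count across conditions is at
#' least \code{k} (so "fewer than k counts everywhere" is removed; the
#' boundary count \code{k} itself is kept). The per-compound maximum is used
#' because cross-condition comparison requires retaining compounds absent in
#' one arm. Condition totals are unchanged (the filter does not renormalise).
#'
#' @param x a \code{\link{count_table}}.
#' @param k minimum count (>= 0); default 3.
#' @return filtered \code{\link{count_table}}.
#' @export
filter_min_count <- function(x, k = 3) {
  stopifnot(inherits(x, "count_table"), k >= 0)
  keep <- apply(x$counts, 1, max) >= k
  count_table(bb = x$bb[keep, , drop = FALSE],
              counts = x$counts[keep, , drop = FALSE],
              totals = x$totals, unmapped = x$unmapped)
}

#' Normalise counts to CPM (sequence counts per million reads)
#'
#' \code{cpm = count / total * 1e6} per condition, with totals including any
#' unmapped reads, so mapped + unmapped CPM sums to 1e6 per condition on an
#' unfiltered table.
#'
#' @param x a \code{\link{count_table}}.
#' @return object of class \code{enrichment_table}: the count table plus a
#'   \code{cpm} matrix and \code{unmapped_cpm}.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "count_table"))
  zero <- x$totals == 0
  if (any(zero))
    stop("zero total reads in condition(s): ",
         paste(x$conditions[zero], collapse = ", "))
  cpm <- sweep(x$counts, 2, x$totals, "/") * 1e6
  structure(c(unclass(x),
              list(cpm = cpm, unmapped_cpm = x$unmapped / x$totals * 1e6)),
            class = c("enrichment_table", "count_table"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  NextMethod()
  if (!is.null(x$selectivity))
    cat(sprintf("  selectivity: log2 %s vs %s (pseudocount %g CPM)\n",
                attr(x$selectivity, "cond_a"), attr(x$selectivity, "cond_b"),
                attr(x$selectivity, "pseudocount")))
  invisible(x)
}

#' Cofactor-selectivity score between two selection conditions
#'
#' Per-compound \code{log2((cpm_a + pc) / (cpm_b + pc))}: positive means
#' enriched under \code{cond_a}, negative under \code{cond_b}; antisymmetric
#' under swapping the conditions and zero when the CPMs are equal.
#'
#' @param x an \code{\link{cpm_normalize}}d enrichment table.
#' @param cond_a,cond_b condition names to compare.
#' @param pseudocount CPM pseudocount keeping the ratio finite; default 1.
#' @return \code{x} with a \code{selectivity} vector added (attributes
#'   record the conditions and pseudocount).
#' @export
selectivity_score <- function(x, cond_a, cond_b, pseudocount = 1) {
  stopifnot(inherits(x, "enrichment_table"), pseudocount > 0)
  for (cc in c(cond_a, cond_b))
    if (!cc %in% x$conditions) stop("condition not in table: ", cc)
  s <- log2((x$cpm[, cond_a] + pseudocount) / (x$cpm[, cond_b] + pseudocount))
  attr(s, "cond_a") <- cond_a
  attr(s, "cond_b") <- cond_b
  attr(s, "pseudocount") <- pseudocount
  x$selectivity <- s
  x
}

#' Aggregate enrichment over building-block projections (synthon view)
#'
#' Projects the compound-level table onto the building blocks at the given
#' positions (mono-, di-, ... synthon aggregation) and sums member CPMs.
#'
#' @param x an \code{\link{cpm_normalize}}d enrichment table.
#' @param positions character vector of position column names to keep.
#' @return data.frame: position columns, \code{n_members}, and one
#'   aggregate-CPM column per condition (named \code{cpm.<condition>}).
#' @export
synthon_aggregate <- function(x, positions) {
  stopifnot(inherits(x, "enrichment_table"))
  if (!length(positions)) stop("empty position set")
  if (!all(positions %in% names(x$bb)))
    stop("positions not in library: ",
         paste(setdiff(positions, names(x$bb)), collapse = ", "))
  key <- interaction(x$bb[positions], drop = TRUE, lex.order = TRUE, sep = "|")
  agg <- rowsum(x$cpm, key)
  ord <- rownames(agg)
  keys <- do.call(rbind, strsplit(ord, "|", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- positions
  out$n_members <- as.integer(table(key)[ord])
  cpm_df <- as.data.frame(agg)
  names(cpm_df) <- paste0("cpm.", colnames(x$cpm))
  rownames(out) <- NULL
  cbind(out, cpm_df)
}

#' Detect building-block series in a scored enrichment table
#'
#' A series is a single-position building-block constraint (the way DEL hit
#' series are defined) whose passing members -- compounds meeting
#' \code{min_cpm} in at least one of the scored conditions and
#' \code{|selectivity| >= min_selectivity} -- number at least
#' \code{min_members}. Clusters are ranked by median member selectivity
#' (descending, so the most cond_a-selective series lead), then aggregate
#' CPM, with residual ties broken lexicographically by building-block id.
#'
#' @param x an enrichment table carrying a \code{\link{selectivity_score}}.
#' @param min_members minimum number of passing member compounds; default 3.
#' @param min_cpm member CPM threshold (in either scored condition).
#' @param min_selectivity member |log2 selectivity| threshold.
#' @return data.frame of class \code{series_table}: \code{position},
#'   \code{building_block}, \code{n_members}, \code{median_selectivity},
#'   \code{aggregate_cpm} (sum over passing members, cond_a), one row per
#'   detected series; member compound ids in \code{attr(, "members")}.
#' @export
detect_series <- function(x, min_members = 3, min_cpm = 0,
                          min_selectivity = 0) {
  stopifnot(inherits(x, "enrichment_table"),
            min_members >= 0, min_cpm >= 0, min_selectivity >= 0)
  if (is.null(x$selectivity))
    stop("run selectivity_score() before detect_series()")
  cond_a <- attr(x$selectivity, "cond_a")
  cond_b <- attr(x$selectivity, "cond_b")
  pass <- pmax(x$cpm[, cond_a], x$cpm[, cond_b]) >= min_cpm &
    abs(x$selectivity) >= min_selectivity
  rows <- list(); members <- list()
  for (p in names(x$bb)) {
    for (b in sort(unique(x$bb[[p]]))) {
      m <- x$bb[[p]] == b & pass
      if (sum(m) < min_members || sum(m) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        position = p, building_block = b, n_members = sum(m),
        median_selectivity = stats::median(x$selectivity[m]),
        aggregate_cpm = sum(x$cpm[m, cond_a]),
        stringsAsFactors = FALSE)
      members[[length(members) + 1]] <- x$compound_id[m]
    }
  }
  if (!length(rows)) {
    out <- data.frame(position = character(), building_block = character(),
                      n_members = integer(), median_selectivity = numeric(),
                      aggregate_cpm = numeric())
  } else {
    out <- do.call(rbind, rows)
    ord <- order(-out$median_selectivity, -out$aggregate_cpm,
                 out$building_block)
    out <- out[ord, , drop = FALSE]
    members <- members[ord]
    rownames(out) <- NULL
  }
  attr(out, "members") <- members
  attr(out, "conditions") <- c(cond_a, cond_b)
  class(out) <- c("series_table", "data.frame")
  out
}

#' A qPCR measurement of one oligonucleotide species
#'
#' @param ct_eluate,ct_input threshold cycles in the selection eluate and
#'   the input material (>= 0).
#' @param efficiency per-cycle amplification efficiency, in (1, 2];
#'   default 2 (perfect doubling).
#' @return object of class \code{qpcr_measurement}.
#' @export
qpcr_measurement <- function(ct_eluate, ct_input, efficiency = 2) {
  stopifnot(ct_eluate >= 0, ct_input >= 0, efficiency > 1, efficiency <= 2)
  structure(list(ct_eluate = ct_eluate, ct_input = ct_input,
                 efficiency = efficiency),
            class = "qpcr_measurement")
}

#' qPCR fold enrichment of a compound conjugate over a reference oligo
#'
#' Double-delta Ct: \code{fold = eff^(dCt_ref - dCt_compound)} with
#' \code{dCt = Ct_eluate - Ct_input}. Equal delta-Cts give fold 1.
#'
#' @param meas_compound,meas_reference \code{\link{qpcr_measurement}}s with
#'   equal amplification efficiencies.
#' @return positive fold enrichment.
#' @examples
#' cmp <- qpcr_measurement(ct_eluate = 12, ct_input = 15)
#' ref <- qpcr_measurement(ct_eluate = 18, ct_input = 18)
#' qpcr_fold_enrichment(cmp, ref)  # 2^3 = 8
#' @export
qpcr_fold_enrichment <- function(meas_compound, meas_reference) {
  stopifnot(inherits(meas_compound, "qpcr_measurement"),
            inherits(meas_reference, "qpcr_measurement"))
  if (meas_compound$efficiency != meas_reference$efficiency)
    stop("amplification efficiencies differ between compound and reference")
  d_cmp <- meas_compound$ct_eluate - meas_compound$ct_input
  d_ref <- meas_reference$ct_eluate - meas_reference$ct_input
  meas_compound$efficiency^(d_ref - d_cmp)
}
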
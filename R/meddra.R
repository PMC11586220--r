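#' Load a PT -> HLGT -> SOC mapping table
#'
#' The event dictionary content is licensed, so the map is user-supplied: a
#' 3-column TSV (`pt`, `hlgt`, `soc`) with a header row. Duplicate PT rows
#' with identical mappings collapse; conflicting duplicates are an error.
#'
#' @param path TSV file path.
#' @param version_label free-text label carried along for provenance.
#' @return object of class `meddra_map` with `entries` (data.frame
#'   `pt, hlgt, soc`) and `version_label`.
#' @export
load_meddra_map <- function(path, version_label = basename(path)) {
  if (!file.exists(path)) stopf("MedDRA map file '%s' not found", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  names(tab) <- tolower(names(tab))
  if (!all(c("pt", "hlgt", "soc") %in% names(tab))) {
    stopf("MedDRA map must have columns pt, hlgt, soc (got: %s)",
          paste(names(tab), collapse = ", "))
  }
  new_meddra_map(tab[, c("pt", "hlgt", "soc")], version_label)
}

new_meddra_map <- function(entries, version_label = "unversioned") {
  entries <- unique(entries)
  if (any(!nzchar(entries$pt)) || any(!nzchar(entries$hlgt)) ||
      any(!nzchar(entries$soc))) {
    stopf("MedDRA map names must be non-empty")
  }
  conflicted <- unique(entries$pt[duplicated(entries$pt)])
  if (length(conflicted)) {
    stopf("conflicting MedDRA mapping for PT(s): %s",
          paste(conflicted, collapse = ", "))
  }
  rownames(entries) <- NULL
  out <- list(entries = entries, version_label = version_label)
  class(out) <- "meddra_map"
  out
}

#' @export
print.meddra_map <- function(x, ...) {
  cat(sprintf("meddra_map '%s': %d PTs, %d HLGTs, %d SOCs\n", x$version_label,
              nrow(x$entries), length(unique(x$entries$hlgt)),
              length(unique(x$entries$soc))))
  invisible(x)
}

#' Aggregate signal case counts to HLGT or SOC proportions
#'
#' Groups signal PTs by the chosen hierarchy level and returns per-group
#' case-count sums and their proportions of the drug's total signal case
#' count. PTs absent from the map are pooled into an `"unmapped"` group.
#'
#' @param signals data.frame with columns `pt` and `a` (case count per
#'   signal), e.g. the signal rows of a [disprop()] fit.
#' @param meddra a `meddra_map`.
#' @param level `"SOC"` or `"HLGT"`.
#' @param weight `"cases"` (sum of case counts, default) or `"signals"`
#'   (number of signal PTs) as the aggregated quantity.
#' @return data.frame `group, cases, proportion`, sorted by decreasing
#'   cases; proportions sum to 1 (over all groups including `"unmapped"`).
#'   Empty input gives a zero-row frame.
#' @export
aggregate_signals <- function(signals, meddra, level = c("SOC", "HLGT"),
                              weight = c("cases", "signals")) {
  level <- match.arg(level)
  weight <- match.arg(weight)
  if (is.null(signals) || nrow(signals) == 0L) {
    return(data.frame(group = character(), cases = numeric(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  }
  col <- if (level == "SOC") "soc" else "hlgt"
  hit <- match(signals$pt, meddra$entries$pt)
  grp <- meddra$entries[[col]][hit]
  grp[is.na(grp)] <- "unmapped"
  w <- if (weight == "cases") signals$a else rep(1, nrow(signals))
  agg <- stats::aggregate(list(cases = w), by = list(group = grp), FUN = sum)
  agg$proportion <- agg$cases / sum(agg$cases)
  agg <- agg[order(-agg$cases, agg$group), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
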
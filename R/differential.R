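# Differential-expression calling and set-level summaries (Venn regions,
# COG category tallies).

#' Call differentially expressed proteins
#'
#' A quantified protein is up-regulated when its median ratio is at least
#' `up_threshold` and down-regulated when it is at most `down_threshold`
#' (both boundaries inclusive).  Proteins that did not pass the
#' quantitation gate keep their status and get direction `none`, so every
#' protein/comparison pair appears explicitly in the output — Venn
#' semantics need explicit absence, not missing rows.
#'
#' @param quants A protein quantitation `data.frame` from
#'   [quantify_proteins()] (or [read_protein_table()]).
#' @param up_threshold,down_threshold Fold-change thresholds; must satisfy
#'   `down_threshold < 1 < up_threshold`.
#' @return A `data.frame` with columns `protein_acc`, `comparison`,
#'   `median_ratio`, `status` and `direction` (`up`, `down` or `none`).
#' @export
call_de <- function(quants, up_threshold = 1.2, down_threshold = 0.83) {
  if (!(is.numeric(up_threshold) && is.numeric(down_threshold) &&
        down_threshold < 1 && 1 < up_threshold))
    stop_config("thresholds must satisfy down_threshold < 1 < up_threshold")
  quantified <- quants$status == "quantified"
  direction <- rep("none", nrow(quants))
  direction[quantified & quants$median_ratio >= up_threshold] <- "up"
  direction[quantified & quants$median_ratio <= down_threshold] <- "down"
  data.frame(protein_acc = quants$protein_acc,
             comparison = quants$comparison,
             median_ratio = quants$median_ratio,
             status = quants$status,
             direction = direction,
             stringsAsFactors = FALSE)
}

#' @noRd
de_accessions <- function(de, comparison = NULL) {
  keep <- de$direction %in% c("up", "down")
  if (!is.null(comparison)) keep <- keep & de$comparison == comparison
  unique(de$protein_acc[keep])
}

#' Three-set Venn region counts
#'
#' Exact cardinalities of the seven regions of a three-set Venn diagram
#' over differentially-expressed accession sets, plus each set's total.
#'
#' @param sets A named list of three character vectors (e.g. the DE
#'   accessions at 50, 100 and 200 mM).
#' @return A list with `sets` (the three set names), `regions` (named
#'   integer vector: `"A_only"`, `"B_only"`, `"C_only"`, `"AB_only"`,
#'   `"AC_only"`, `"BC_only"`, `"ABC"`, where A/B/C are the set names in
#'   input order) and `totals`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3L) stop_validation("venn_counts expects exactly 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- c("A", "B", "C")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1L]]
  inB <- universe %in% sets[[2L]]
  inC <- universe %in% sets[[3L]]
  nm <- names(sets)
  regions <- c(
    sum(inA & !inB & !inC), sum(!inA & inB & !inC), sum(!inA & !inB & inC),
    sum(inA & inB & !inC), sum(inA & !inB & inC), sum(!inA & inB & inC),
    sum(inA & inB & inC))
  names(regions) <- c(paste0(nm, "_only"),
                      paste0(c(paste(nm[1L], nm[2L], sep = ":"),
                               paste(nm[1L], nm[3L], sep = ":"),
                               paste(nm[2L], nm[3L], sep = ":")), "_only"),
                      paste(nm, collapse = ":"))
  totals <- vapply(sets, length, 0L)
  list(sets = nm, regions = regions, totals = totals)
}

#' Tally differentially expressed proteins by COG category
#'
#' Counts each distinct DE accession (union over comparisons) once in its
#' COG functional category; proteins without a COG annotation are counted
#' under `no_hit` ("no significant similarity").
#'
#' @param de A DE call `data.frame` from [call_de()].
#' @param ann An [annotation_map()].
#' @return A named integer vector over [COG_CATEGORIES] (zero-filled).
#' @export
cog_tally <- function(de, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  accs <- de_accessions(de)
  cats <- ann$cog[accs]
  cats[is.na(cats)] <- "no_hit"
  tally <- table(factor(cats, levels = COG_CATEGORIES))
  out <- as.integer(tally)
  names(out) <- COG_CATEGORIES
  out
}
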
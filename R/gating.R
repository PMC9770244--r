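# Volume distributions, viable-cell gating, per-larva tumour-burden
# summaries and group comparison.

#' Volume gate for viable cells
#'
#' Objects with volume strictly above `minVolume` (and strictly below
#' `maxVolume` when set) pass the gate.  The default lower bound of
#' 1000 um^3 separates viable cells from apoptotic fragments and debris;
#' the boundary is exclusive, so an object of exactly 1000 um^3 is gated
#' out.  Per-study thresholds should be read off the volume distribution of
#' the day-of-injection images for the cell line at hand.
#'
#' @param minVolume lower volume bound, um^3, `>= 0`.
#' @param maxVolume optional upper bound, um^3, `> minVolume`.
#' @return list with class `"VolumeGate"`.
#' @export
volumeGate <- function(minVolume = 1000, maxVolume = NULL) {
  stopifnot(minVolume >= 0, is.null(maxVolume) || maxVolume > minVolume)
  structure(list(minVolume = as.numeric(minVolume),
                 maxVolume = if (is.null(maxVolume)) NULL
                             else as.numeric(maxVolume)),
            class = "VolumeGate")
}

#' Apply a volume gate to an object table
#'
#' @param objects data.frame with a `volume_um3` column.
#' @param gate a [volumeGate()].
#' @return the gated subset, order preserved.
#' @export
gateObjects <- function(objects, gate = volumeGate()) {
  stopifnot(inherits(gate, "VolumeGate"))
  keep <- objects$volume_um3 > gate$minVolume
  if (!is.null(gate$maxVolume)) keep <- keep & objects$volume_um3 < gate$maxVolume
  objects[keep, , drop = FALSE]
}

#' Volume histogram with below/above-gate partition
#'
#' Counts objects per volume bin, with explicit underflow and overflow bins
#' so every object lands in exactly one bin, and splits each bin's count at
#' the gate (fragments below, viable cells above), mirroring the white /
#' grey split of published volume-distribution plots.
#'
#' @param objects data.frame with `volume_um3`.
#' @param binEdges strictly increasing numeric vector of bin edges, um^3;
#'   interior bins are `[e_i, e_{i+1})`.
#' @param gate a [volumeGate()] used only for the partition columns.
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `n_below_gate`,
#'   `n_above_gate`; first and last rows are the underflow/overflow bins.
#' @export
volumeHistogram <- function(objects, binEdges, gate = volumeGate()) {
  if (length(binEdges) < 1L || is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must be non-empty and strictly increasing")
  edges <- c(-Inf, binEdges, Inf)
  v <- objects$volume_um3
  bin <- findInterval(v, edges, left.open = FALSE)  # in 1..length(edges)-1
  nb <- length(edges) - 1L
  inGate <- v > gate$minVolume &
    (is.null(gate$maxVolume) | v < (gate$maxVolume %||% Inf))
  data.frame(
    bin_lo = edges[seq_len(nb)],
    bin_hi = edges[-1L],
    n = tabulate(bin, nb),
    n_below_gate = tabulate(bin[!inGate], nb),
    n_above_gate = tabulate(bin[inGate], nb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-larva record of segmented objects
#'
#' @param larvaId,group,dpi identifiers (dpi integer `>= 0`).
#' @param objects data.frame from [measureObjects()]; labels must be
#'   unique within the record.
#' @return list with class `"LarvaRecord"`.
#' @export
larvaRecord <- function(larvaId, group, dpi, objects) {
  stopifnot(dpi >= 0)
  if (anyDuplicated(objects$label))
    stop("object labels must be unique within a larva record")
  structure(list(larvaId = as.character(larvaId), group = as.character(group),
                 dpi = as.integer(dpi), objects = objects),
            class = "LarvaRecord")
}

#' Split an objects table into per-(larva, dpi) records
#' @param objects combined objects data.frame (e.g. several CSVs row-bound).
#' @return list of [larvaRecord()]s.
#' @export
asLarvaRecords <- function(objects) {
  if (nrow(objects) == 0L) return(list())
  key <- paste(objects$larva_id, objects$dpi, sep = "\r")
  lapply(split(objects, key), function(df)
    larvaRecord(df$larva_id[1L], df$group[1L], df$dpi[1L], df))
}

#' Summarise tumour burden per larva and day
#'
#' For each (larva, dpi): the gated cell count, the gated total volume
#' (the filtered total cell volume) and the ungated total volume of all
#' segmented objects.  Totals are exact sums over the record's objects.
#'
#' @param records list of [larvaRecord()]s.
#' @param gate a [volumeGate()].
#' @return data.frame with one row per (larva, dpi): `larva_id`, `group`,
#'   `dpi`, `cell_count`, `gated_volume_um3`, `total_volume_um3`.
#' @export
summarizeBurden <- function(records, gate = volumeGate()) {
  keys <- vapply(records, function(r) paste(r$larvaId, r$dpi, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate (larva, dpi) records")
  rows <- lapply(records, function(r) {
    g <- gateObjects(r$objects, gate)
    data.frame(larva_id = r$larvaId, group = r$group, dpi = r$dpi,
               cell_count = nrow(g),
               gated_volume_um3 = sum(g$volume_um3),
               total_volume_um3 = sum(r$objects$volume_um3))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Welch's t-test between two groups
#'
#' Two-tailed Welch's (unequal-variance) t-test with Welch–Satterthwaite
#' degrees of freedom, as used for per-day burden and heart-rate group
#' comparisons.  No multiple-testing correction is applied across days.
#'
#' @param sampleA,sampleB numeric vectors, each `n >= 2` with non-zero
#'   variance.
#' @return list with `t`, `df`, `p`.
#' @export
welchTest <- function(sampleA, sampleB) {
  if (length(sampleA) < 2L || length(sampleB) < 2L)
    stop("each sample needs n >= 2")
  if (stats::var(sampleA) == 0 && stats::var(sampleB) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(sampleA, sampleB, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
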
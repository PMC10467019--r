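#' Percentage contributions of each current to its inward/outward class
#'
#' At every time step, membrane currents are split by sign: negative samples
#' are inward, positive are outward, exact zeros belong to neither class.
#' Each current's contribution is expressed as a percentage of the summed
#' magnitude of its class at that step, so contributions per class sum to 100
#' wherever the class total is nonzero. The injected current is never part of
#' either class; the passive (leak) current is included by default and can be
#' excluded.
#'
#' @param sim A `sim_result` (or anything with `time_ms` and an `I_nA` matrix
#'   of per-channel currents, positive = outward).
#' @param include_passive Include the passive current (`"leak"`/`"pas"`
#'   column) in the class totals (default `TRUE`).
#' @return A `percent_contribution`: `time_ms`, `channels`, matrices `pct_in`
#'   and `pct_out` (n x channels, percent), `total_inward_nA`,
#'   `total_outward_nA` (class totals as magnitudes), and logical masks
#'   `defined_in`, `defined_out` marking samples whose class total is nonzero.
#' @export
percent_contributions <- function(sim, include_passive = TRUE) {
  I <- sim$I_nA
  stopifnot(is.matrix(I), !is.null(colnames(I)))
  if (!include_passive)
    I <- I[, !colnames(I) %in% c("leak", "pas"), drop = FALSE]
  if (ncol(I) < 1L)
    stop("need at least one membrane current beyond the injected current")
  inward <- ifelse(I < 0, -I, 0) # magnitudes
  outward <- ifelse(I > 0, I, 0)
  tot_in <- rowSums(inward)
  tot_out <- rowSums(outward)
  def_in <- tot_in > 0
  def_out <- tot_out > 0
  pct_in <- 100 * inward / ifelse(def_in, tot_in, NA_real_)
  pct_out <- 100 * outward / ifelse(def_out, tot_out, NA_real_)
  structure(
    list(time_ms = sim$time_ms, channels = colnames(I),
         pct_in = pct_in, pct_out = pct_out,
         total_inward_nA = tot_in, total_outward_nA = tot_out,
         defined_in = def_in, defined_out = def_out),
    class = "percent_contribution")
}

#' @export
print.percent_contribution <- function(x, ...) {
  cat(sprintf(
    "<percent_contribution> %d samples, %d channels (%s); inward defined %.1f%%, outward %.1f%%\n",
    length(x$time_ms), length(x$channels), paste(x$channels, collapse = ", "),
    100 * mean(x$defined_in), 100 * mean(x$defined_out)))
  invisible(x)
}

#' Intervals of constant inward/outward class for one channel
#'
#' A channel near its reversal potential can flip between contributing inward
#' and outward current; this reports the maximal time intervals over which its
#' class is constant (classes: `"inward"`, `"outward"`, `"none"` for exact
#' zeros).
#'
#' @param pc A [percent_contributions()] result.
#' @param channel Channel name.
#' @return Data frame with `start_ms`, `end_ms`, `class`.
#' @export
class_flip_report <- function(pc, channel) {
  stopifnot(inherits(pc, "percent_contribution"))
  j <- match(channel, pc$channels)
  if (is.na(j)) stop(sprintf("unknown channel '%s'", channel))
  cls <- rep("none", length(pc$time_ms))
  inw <- !is.na(pc$pct_in[, j]) & pc$pct_in[, j] > 0
  outw <- !is.na(pc$pct_out[, j]) & pc$pct_out[, j] > 0
  cls[inw] <- "inward"
  cls[outw] <- "outward"
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(start_ms = pc$time_ms[starts], end_ms = pc$time_ms[ends],
             class = r$values, stringsAsFactors = FALSE)
}

#' Write a percentage-contribution table as delimited text
#'
#' Columns: `time_ms`, `pct_in_<channel>`/`pct_out_<channel>` per channel,
#' then the class totals. Undefined samples are written as the sentinel `NA`.
#'
#' @param pc A [percent_contributions()] result.
#' @param path File path.
#' @export
write_contributions <- function(pc, path) {
  df <- data.frame(time_ms = pc$time_ms, check.names = FALSE)
  for (ch in pc$channels) {
    j <- match(ch, pc$channels)
    df[[paste0("pct_in_", ch)]] <- pc$pct_in[, j]
    df[[paste0("pct_out_", ch)]] <- pc$pct_out[, j]
  }
  df$total_inward_nA <- pc$total_inward_nA
  df$total_outward_nA <- pc$total_outward_nA
  hdr <- c("# fdgscape percent contributions",
           "# undefined samples (zero class total) are written as NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
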
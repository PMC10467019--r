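#' Write / read a simulation trace table as delimited text
#'
#' Columns `time_ms`, `I_inj_nA`, `V_mV`, then one column per channel current
#' (`I_<name>_nA`, positive = outward). Values are printed with 17 significant
#' digits so that write-then-read round-trips bitwise. The header comments
#' carry the tool version and a provenance hash of the generating parameters.
#'
#' @param sim A `sim_result`.
#' @param path File path.
#' @param sep Field delimiter (default tab; readers accept tab, comma or
#'   whitespace).
#' @export
write_trace <- function(sim, path, sep = "\t") {
  stopifnot(inherits(sim, "sim_result"))
  chan_cols <- paste0("I_", colnames(sim$I_nA), "_nA")
  hdr <- c("# fdgscape trace table",
           sprintf("# version=%s config_hash=%s",
                   as.character(utils::packageVersion("fdgscape")),
                   provenance_hash(sim$params)),
           paste(c("time_ms", "I_inj_nA", "V_mV", chan_cols), collapse = sep))
  cols <- cbind(sim$time_ms, sim$I_inj_nA, sim$V_mV, sim$I_nA)
  body <- apply(cols, 1, function(row)
    paste(sprintf("%.17g", row), collapse = sep))
  writeLines(c(hdr, body), path)
  invisible(path)
}

provenance_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @rdname write_trace
#' @return `read_trace` returns a `trace_table`: a data frame of the columns
#'   with attributes `dt_ms` and `header` (the comment lines).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  first <- body[1]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          check.names = FALSE)
  tcol <- grep("^(time|t)($|_ms)", names(df), value = TRUE)[1]
  if (is.na(tcol)) stop("format error: no time column found")
  tt <- df[[tcol]]
  if (length(tt) < 2L) stop("format error: need at least 2 rows")
  dts <- diff(tt)
  dt <- dts[1]
  bad <- which(abs(dts - dt) > 1e-9 * max(abs(dt), 1))
  if (length(bad))
    stop(sprintf("format error: non-uniform time grid at row %d (dt %.9g vs %.9g)",
                 bad[1] + 1L, dts[bad[1]], dt))
  structure(df, dt_ms = dt, header = hdr, class = c("trace_table",
                                                    "data.frame"))
}

#' Default NEURON channel-name canonicalisation map
#'
#' Maps the current-column names used by detailed cortical pyramidal-cell
#' models in the NEURON ecosystem to this package's canonical labels.
#'
#' @return Named character vector (file name -> canonical name).
#' @export
default_channel_map <- function() {
  c(Na_Ta_t = "NaT", NaTa_t = "NaT", Nap_Et2 = "NaP", K_Pst = "K_Pst",
    SKv3_1 = "SKv3_1", SK_E2 = "SK_E2", K_Tst = "K_Tst", Ca_LVA = "Ca_LVA",
    Ca_LVAst = "Ca_LVA", Ca_HVA = "Ca_HVA", Ih = "Ih", Im = "Im",
    pas = "pas",
    # this package's own synthetic channel names (loop-back imports)
    leak = "pas", NaT = "NaT", Kfast = "Kfast", Kslow = "Kslow")
}

#' Import a NEURON-exported somatic trace table as a simulation result
#'
#' Reads a delimited text export (time, voltage, per-current columns), renames
#' current columns through `channel_name_map`, and checks the sign convention:
#' if the file's sodium/h currents are predominantly positive at subthreshold
#' voltages the file used positive = inward, and all currents are flipped to
#' this package's positive = outward convention with a warning.
#'
#' @param path Path to the exported trace table.
#' @param channel_name_map Named character vector mapping file column names to
#'   canonical channel names (default [default_channel_map()]). Every current
#'   column in the file must be covered.
#' @return A `sim_result` usable by all downstream analyses ([detect_spikes()],
#'   [percent_contributions()], ...). `params` is `NULL` (unknown model).
#' @export
import_neuron_export <- function(path, channel_name_map = default_channel_map()) {
  tt <- read_trace(path)
  nms <- names(tt)
  tcol <- grep("^(time|t)($|_ms)", nms, value = TRUE)[1]
  vcol <- grep("^(V|v)($|_mV|_soma)", nms, value = TRUE)[1]
  if (is.na(vcol)) stop("format error: no voltage column found")
  icol <- grep("^I_inj", nms, value = TRUE)[1]
  cur_cols <- setdiff(nms, c(tcol, vcol, icol))
  cur_names <- sub("_nA$", "", sub("^I_", "", cur_cols))
  unmapped <- setdiff(cur_names, names(channel_name_map))
  if (length(unmapped))
    stop(sprintf("unmapped current column(s): %s",
                 paste(unmapped, collapse = ", ")))
  I <- as.matrix(tt[cur_cols])
  colnames(I) <- unname(channel_name_map[cur_names])
  V <- tt[[vcol]]
  # sign check on currents that are physiologically inward at subthreshold V
  sub <- V < -55
  probes <- intersect(colnames(I), c("NaT", "NaP", "Ih"))
  if (any(sub) && length(probes)) {
    med <- stats::median(I[sub, probes, drop = FALSE][I[sub, probes] != 0])
    if (is.finite(med) && med > 0) {
      warning("inward currents positive at subthreshold V: flipping sign convention to positive = outward")
      I <- -I
    }
  }
  structure(
    list(time_ms = tt[[tcol]], V_mV = V, I_nA = I,
         I_inj_nA = if (!is.na(icol)) tt[[icol]] else
           rep(NA_real_, length(V)),
         dt_ms = attr(tt, "dt_ms"), params = NULL,
         stim_spec = NULL),
    class = "sim_result")
}
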
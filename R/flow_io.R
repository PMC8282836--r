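#' @keywords internal
"_PACKAGE"

# Canonical column schema for per-cell tables of calibrated fluorescence.
CONDITION_COLS <- c("topology", "flp_ng", "shrna_ng", "dox_nM", "time_h", "replicate")
CHANNEL_COLS   <- c("cfp", "ifp", "ofp")
TOPOLOGIES     <- c("NO_SHRNA", "CONSTANT", "FEEDFORWARD")

#' Fluorescence channels
#'
#' Names of the three calibrated fluorescence channels carried by every
#' cell record: \code{cfp} (constitutive marker, correlates with plasmid
#' copy number), \code{ifp} (input proxy reporting pTRE transcriptional
#' activity) and \code{ofp} (digitizer output). All values are in MEFL
#' (Molecules of Equivalent Fluorescein).
#'
#' @return Character vector of channel names.
#' @export
channels <- function() CHANNEL_COLS

#' Construct a condition descriptor
#'
#' A condition identifies one experimental population: circuit topology,
#' plasmid masses of the Flp and shRNA units, doxycycline concentration,
#' time post transfection/induction, and replicate index.
#'
#' @param topology One of \code{"NO_SHRNA"}, \code{"CONSTANT"},
#'   \code{"FEEDFORWARD"}.
#' @param flp_ng,shrna_ng Plasmid masses (ng); non-negative.
#' @param dox_nM Doxycycline concentration (nM); non-negative.
#' @param time_h Hours post transfection/induction; non-negative.
#' @param replicate Integer replicate index.
#' @return A named list of class \code{"condition"}.
#' @export
condition <- function(topology, flp_ng, shrna_ng = 0, dox_nM = 0,
                      time_h = 48, replicate = 1L) {
  topology <- match.arg(topology, TOPOLOGIES)
  stopifnot(flp_ng >= 0, shrna_ng >= 0, dox_nM >= 0, time_h >= 0)
  if (topology == "NO_SHRNA" && shrna_ng != 0)
    stop("topology NO_SHRNA requires shrna_ng = 0")
  structure(list(topology = topology, flp_ng = flp_ng, shrna_ng = shrna_ng,
                 dox_nM = dox_nM, time_h = time_h,
                 replicate = as.integer(replicate)),
            class = "condition")
}

#' Construct a sample population
#'
#' Bundles per-cell fluorescence records with the condition they were
#' measured under. Record order is preserved throughout gating and
#' filtering (ties at gate boundaries are broken by input order).
#'
#' @param records Data frame with numeric columns \code{cfp}, \code{ifp},
#'   \code{ofp} (MEFL), one row per cell event.
#' @param condition A \code{\link{condition}} object.
#' @return Object of class \code{"sample_population"}.
#' @export
sample_population <- function(records, condition) {
  stopifnot(is.data.frame(records), inherits(condition, "condition"))
  missing <- setdiff(CHANNEL_COLS, names(records))
  if (length(missing))
    stop("records missing channel column(s): ", paste(missing, collapse = ", "))
  for (ch in CHANNEL_COLS) {
    v <- records[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("channel '", ch, "' must be finite numeric")
  }
  structure(list(condition = condition,
                 records = records[, CHANNEL_COLS, drop = FALSE]),
            class = "sample_population")
}

#' @export
print.sample_population <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("<sample_population> %d cells | %s flp=%gng shrna=%gng dox=%gnM t=%gh rep=%d\n",
              nrow(x$records), cn$topology, cn$flp_ng, cn$shrna_ng,
              cn$dox_nM, cn$time_h, cn$replicate))
  invisible(x)
}

#' Number of cell events in a population
#' @param pop A \code{sample_population}.
#' @return Integer count.
#' @export
n_cells <- function(pop) nrow(pop$records)

#' Extract one channel from a population
#' @param pop A \code{sample_population}.
#' @param channel Channel name; see \code{\link{channels}}.
#' @return Numeric vector of MEFL values in record order.
#' @export
channel_values <- function(pop, channel) {
  if (!channel %in% CHANNEL_COLS)
    stop("unknown channel '", channel, "'; valid channels: ",
         paste(CHANNEL_COLS, collapse = ", "))
  pop$records[[channel]]
}

validate_experiment_table <- function(df) {
  need <- c(CONDITION_COLS, CHANNEL_COLS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("table missing required column(s): ", paste(missing, collapse = ", "))
  bad_top <- setdiff(unique(df$topology), TOPOLOGIES)
  if (length(bad_top))
    stop("unknown topology value(s): ", paste(bad_top, collapse = ", "))
  for (ch in CHANNEL_COLS) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric value in column '", ch, "' at data row ", bad)
    }
  }
  df
}

#' Read a per-cell fluorescence table
#'
#' Reads a delimited text file (comma- or tab-separated, autodetected from
#' the \code{.csv}/\code{.tsv} extension) with one row per cell event and
#' the canonical columns \code{topology, flp_ng, shrna_ng, dox_nM, time_h,
#' replicate, cfp, ifp, ofp}. Row order within each condition is preserved.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(ofp = "GFP_MEFL")}.
#' @return An \code{experiment_table}: a data frame in the canonical schema
#'   (one row per cell) that groups into populations via
#'   \code{\link{split_populations}}.
#' @export
read_population_table <- function(path, schema = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA,
                          check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("schema maps '", canon, "' to missing column '", schema[[canon]], "'")
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  df <- validate_experiment_table(df)
  for (ch in c(CHANNEL_COLS, "flp_ng", "shrna_ng", "dox_nM", "time_h"))
    df[[ch]] <- as.numeric(df[[ch]])
  df$replicate <- as.integer(df$replicate)
  key <- interaction(df[CONDITION_COLS], drop = TRUE)
  class(df) <- c("experiment_table", "data.frame")
  attr(df, "n_populations") <- nlevels(key)
  df
}

#' Write a per-cell fluorescence table
#'
#' Inverse of \code{\link{read_population_table}}. Fluorescence values are
#' written with 17 significant digits so that a write/read round trip is
#' bit-exact for doubles.
#'
#' @param table An \code{experiment_table} (or data frame in the canonical
#'   schema).
#' @param path Output path; extension selects the delimiter.
#' @return \code{path}, invisibly.
#' @export
write_population_table <- function(table, path) {
  table <- validate_experiment_table(as.data.frame(table))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- table[, c(CONDITION_COLS, CHANNEL_COLS)]
  for (ch in c(CHANNEL_COLS, "flp_ng", "shrna_ng", "dox_nM", "time_h"))
    out[[ch]] <- sprintf("%.17g", out[[ch]])
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split an experiment table into sample populations
#'
#' @param table An \code{experiment_table} or data frame in the canonical
#'   schema.
#' @return Named list of \code{\link{sample_population}} objects, one per
#'   unique (condition, replicate) key, in first-appearance order. Errors
#'   on duplicate keys split across non-contiguous blocks are not possible
#'   because grouping is by value.
#' @export
split_populations <- function(table) {
  df <- validate_experiment_table(as.data.frame(table))
  key <- do.call(paste, c(df[CONDITION_COLS], sep = "|"))
  ord_keys <- unique(key)
  out <- lapply(ord_keys, function(k) {
    rows <- df[key == k, , drop = FALSE]
    cn <- condition(rows$topology[1], rows$flp_ng[1], rows$shrna_ng[1],
                    rows$dox_nM[1], rows$time_h[1], rows$replicate[1])
    sample_population(rows[, CHANNEL_COLS], cn)
  })
  names(out) <- ord_keys
  out
}

#' Assemble an experiment table from populations
#'
#' @param pops List of \code{\link{sample_population}} objects.
#' @return An \code{experiment_table} data frame in the canonical schema.
#' @export
bind_populations <- function(pops) {
  rows <- lapply(pops, function(p) {
    cn <- p$condition
    cbind(data.frame(topology = cn$topology, flp_ng = cn$flp_ng,
                     shrna_ng = cn$shrna_ng, dox_nM = cn$dox_nM,
                     time_h = cn$time_h, replicate = cn$replicate,
                     stringsAsFactors = FALSE),
          p$records)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("experiment_table", "data.frame")
  df
}

#' Remove sub-threshold events
#'
#' Retains cell events whose constitutive-marker (CFP) fluorescence is at
#' or above \code{floor}, a simple stand-in for live/transfected-cell
#' gating applied upstream of analysis. The number of removed events is
#' reported via \code{message()}.
#'
#' @param pop A \code{\link{sample_population}}.
#' @param floor Detection floor (MEFL), non-negative. Default 1 MEFL so
#'   that downstream log-domain metrics see positive values.
#' @return Filtered \code{sample_population}; errors if no events survive.
#' @export
filter_valid_events <- function(pop, floor = 1) {
  stopifnot(inherits(pop, "sample_population"), floor >= 0)
  keep <- pop$records$cfp >= floor
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("filter_valid_events: removed %d of %d events below floor %g MEFL",
                    removed, length(keep), floor))
  if (!any(keep))
    stop("filter_valid_events: all ", length(keep), " events below floor ", floor)
  sample_population(pop$records[keep, , drop = FALSE], pop$condition)
}

#' Gate the top fraction of a channel
#'
#' Retains the \code{ceiling(fraction * n)} events with the highest values
#' in \code{channel}. This implements the convention of analyzing the top
#' 30\% of CFP-expressing cells, which selects well-transfected cells
#' (CFP correlates with plasmid copy number). Ties at the gate boundary
#' are broken by stable input order; every retained value is >= every
#' discarded value.
#'
#' @param pop A \code{\link{sample_population}}.
#' @param channel Channel to gate on (default \code{"cfp"}).
#' @param fraction Proportion in (0, 1] of events to keep (default 0.30).
#' @return Gated \code{sample_population} preserving input record order.
#' @export
gate_top_fraction <- function(pop, channel = "cfp", fraction = 0.30) {
  stopifnot(inherits(pop, "sample_population"),
            fraction > 0, fraction <= 1)
  v <- channel_values(pop, channel)
  n <- length(v)
  if (n == 0) stop("gate_top_fraction: empty population")
  k <- ceiling(fraction * n)
  # stable: order by decreasing value, ties by original index
  ord <- order(-v, seq_len(n))
  keep <- sort(ord[seq_len(k)])
  sample_population(pop$records[keep, , drop = FALSE], pop$condition)
}

#' Convert doxycycline mass concentration to molarity
#'
#' Doxycycline molecular weight is fixed at 444.44 g/mol, so 100 ng/mL
#' corresponds to 225 nM (the standard induced-media concentration).
#'
#' @param ng_per_ml Concentration in ng/mL; non-negative.
#' @return Concentration in nM.
#' @export
dox_mass_to_molar <- function(ng_per_ml) {
  if (any(ng_per_ml < 0)) stop("dox_mass_to_molar: negative concentration")
  ng_per_ml / 444.44 * 1000
}
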
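#' Write a stimulus-event table to tab-separated text
#'
#' Column layout follows the BIDS events.tsv dialect used throughout the
#' package: `onset` (seconds), `stimulus_id` (0-based), `is_target`
#' (0/1), `block`, `repetition`, `paradigm`.
#'
#' @param events Event table as returned by [generate_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  .validate_events(events)
  out <- events
  out$is_target <- as.integer(out$is_target)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stimulus-event table from tab-separated text
#'
#' @param path Path to a file written by [write_events()].
#' @return Event table data frame; errors name the offending column if
#'   the file violates the format or its invariants (strictly
#'   increasing onsets, complete stimulus sets per repetition, one
#'   target per block).
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("onset", "stimulus_id", "is_target", "block",
                "repetition", "paradigm")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("event file parse error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  ev$is_target <- as.logical(ev$is_target)
  ev <- ev[required]
  .validate_events(ev)
  ev
}

.validate_events <- function(ev) {
  if (!is.numeric(ev$onset) || any(diff(ev$onset) <= 0))
    stop("event file parse error: onset must be strictly increasing",
         call. = FALSE)
  if (anyNA(ev$is_target))
    stop("event file parse error: is_target must be 0/1", call. = FALSE)
  for (b in unique(ev$block)) {
    eb <- ev[ev$block == b, ]
    tgt <- unique(eb$stimulus_id[eb$is_target])
    if (length(tgt) != 1)
      stop("event file parse error: block ", b,
           " must have exactly one target stimulus_id", call. = FALSE)
  }
  invisible(ev)
}
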
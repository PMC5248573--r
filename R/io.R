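# Plain-text interchange: long-format trace CSVs with JSON sidecars, and
# call/summary tables.

#' Convert a trace panel to a long-format table
#'
#' @param panel A `trace_panel`.
#' @return data.frame (`cell_id`, `frame`, `time_h`, `geminin`, `alive`,
#'   `event` in `{none, division, death}`).
#' @export
as_trace_table <- function(panel) {
  traces <- if (inherits(panel, "trace_panel")) panel$traces else panel
  do.call(rbind, lapply(traces, function(tr) {
    n <- length(tr$times)
    event <- rep("none", n)
    ev <- tr$annotated_events
    if (!is.null(ev) && nrow(ev) > 0) {
      for (r in seq_len(nrow(ev))) {
        i <- which.min(abs(tr$times - ev$time[r]))
        event[i] <- ev$kind[r]
      }
    }
    data.frame(cell_id = tr$cell_id, frame = seq_len(n) - 1L,
               time_h = tr$times, geminin = tr$geminin, alive = tr$alive,
               event = event)
  }))
}

#' Write a trace panel to CSV with a JSON sidecar
#'
#' @param panel A `trace_panel`. @param path Output CSV path; the sidecar
#'   (preset, parameters and seed) is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(panel, path) {
  utils::write.csv(as_trace_table(panel), path, row.names = FALSE)
  meta <- attr(panel, "meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a long-format trace CSV into a trace panel
#'
#' @param path CSV path with columns `cell_id`, `time_h`, `geminin`, `alive`
#'   and optionally `event`.
#' @return A `trace_panel` (without ground-truth labels).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  traces <- lapply(split(d, d$cell_id), function(cd) {
    cd <- cd[order(cd$time_h), ]
    ev <- NULL
    if ("event" %in% names(cd)) {
      has <- cd$event %in% c("division", "death")
      if (any(has)) ev <- data.frame(time = cd$time_h[has],
                                     kind = cd$event[has])
    }
    cell_trace(cd$cell_id[1], cd$time_h, cd$geminin, as.logical(cd$alive),
               annotated_events = ev)
  })
  names(traces) <- NULL
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side)
  structure(list(traces = traces, truth = NULL), class = "trace_panel",
            meta = meta)
}
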
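# Convenience pipeline: run the simulate -> group -> classify -> cut chain
# in bounded chunks until a target number of selected events is reached.
# Chunking keeps the raw hit list (dominated by front-plane stops) small.

#' Accumulate selected events of one modality
#'
#' Repeatedly simulates short acquisitions and extracts the selected events
#' of the requested mode until `target_n` events are collected (or
#' `max_chunks` chunks have been simulated).  Emitted-photon bookkeeping is
#' summed across chunks so [absolute_efficiency()] stays valid.
#'
#' @param sources list of [source_spec()] (or one).
#' @param setup a `hcc_setup`.
#' @param mode `"compton"`, `"pinhole"` or `"pet"`.
#' @param target energy-cut target for compton/pinhole (see
#'   [energy_cut()]); for pet the 471--551 keV window is used.
#' @param target_n stop after collecting at least this many events.
#' @param chunk_s simulated seconds per chunk and angle.
#' @param max_chunks safety bound on the number of chunks.
#' @param phantoms,blur,window_ns passed to the underlying chain.
#' @return the concatenated event data.frame of the mode, with attribute
#'   `emitted` (summed per-line photon counts) and `n_chunks`.
#' @export
collect_mode_events <- function(sources, setup,
                                mode = c("compton", "pinhole", "pet"),
                                target = NULL, target_n = 1e4, chunk_s = 10,
                                max_chunks = 200, phantoms = NULL,
                                blur = TRUE, window_ns = 100) {
  mode <- match.arg(mode)
  out <- list()
  emitted <- NULL
  n_got <- 0
  n_chunks <- 0
  while (n_got < target_n && n_chunks < max_chunks) {
    n_chunks <- n_chunks + 1
    hits <- simulate_acquisition(sources, setup, phantoms = phantoms,
                                 duration_s = chunk_s, blur = blur)
    em <- attr(hits, "emitted")
    emitted <- if (is.null(emitted)) em else {
      m <- merge(emitted, em, by = c("nuclide", "energy_kev", "kind"),
                 suffixes = c("", ".new"))
      m$n_emitted <- m$n_emitted + m$n_emitted.new
      m[, c("nuclide", "energy_kev", "kind", "n_emitted")]
    }
    ev <- group_coincidences(hits, window_ns)
    sel <- switch(mode,
                  compton = extract_compton_events(ev, setup, target),
                  pinhole = extract_pinhole_events(ev, setup, target),
                  pet = pair_pet_events(ev, setup))
    if (nrow(sel)) {
      out[[length(out) + 1L]] <- sel
      n_got <- n_got + nrow(sel)
    }
  }
  res <- as.data.frame(data.table::rbindlist(out))
  attr(res, "emitted") <- emitted
  attr(res, "n_chunks") <- n_chunks
  res
}
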
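# Dwell events and residence-time statistics.
#
# A dwell event is a maximal run of consecutive contact frames for one
# (residue, lipid) pair. Its residence time is the literal difference of the
# final and initial frame times, t_res = t_f - t_i = (k - 1) * dt for a
# k-frame run — so an isolated single-frame contact has t_res = 0. This
# differs from the "occupancy time" convention k * dt; the choice matters
# when comparing against published numbers.

#' Extract residue-lipid dwell events
#'
#' @param series a [contact_series()].
#' @param species optional lipid species filter (e.g. `"POPA"`).
#' @param residues residues to consider: `NULL` (default) uses the residues in
#'   stable membrane contact for more than `stable_threshold` of the frames;
#'   `"all"` uses every residue; or a tibble/data frame with `chain` and
#'   `resnum` columns.
#' @param stable_threshold threshold used when `residues` is `NULL`.
#' @param gap_frames number of non-contact frames tolerated inside an event
#'   before it is split (default 0: any gap splits).
#' @return tibble of events: `chain`, `resnum`, `resname`, `lipid_id`,
#'   `species`, `t_i_ps`, `t_f_ps`, `t_res_ps`, `n_frames`, `censored`
#'   (touching either trajectory end). Attribute `dt` carries the frame
#'   spacing.
#' @export
dwell_events <- function(series, species = NULL, residues = NULL,
                         stable_threshold = 0.5, gap_frames = 0L) {
  stopifnot(inherits(series, "contact_series"))
  if (gap_frames < 0L) abort("`gap_frames` must be >= 0.")
  arr <- series$contact
  res_tab <- series$residues
  if (is.null(residues)) {
    p <- contact_probability(series)
    keep_tab <- stable_residues(p, stable_threshold)
    res_idx <- which(paste(res_tab$chain, res_tab$resnum) %in%
                       paste(keep_tab$chain, keep_tab$resnum))
  } else if (identical(residues, "all")) {
    res_idx <- seq_len(nrow(res_tab))
  } else {
    res_idx <- which(paste(res_tab$chain, res_tab$resnum) %in%
                       paste(residues$chain, residues$resnum))
  }
  lip_tab <- series$lipids
  lip_idx <- seq_len(nrow(lip_tab))
  if (!is.null(species)) {
    lip_idx <- which(lip_tab$resname %in% species)
    if (!length(lip_idx)) {
      warn(sprintf("No lipids of species %s; returning empty event list.",
                   paste(species, collapse = ",")))
    }
  }
  times <- series$times
  nf <- dim(arr)[3]
  rows <- list()
  for (ri in res_idx) {
    for (li in lip_idx) {
      v <- arr[ri, li, ]
      if (!any(v)) next
      if (gap_frames > 0L) {
        # bridge interior gaps of <= gap_frames non-contact frames
        r <- rle(v)
        k <- length(r$values)
        bridge <- !r$values & r$lengths <= gap_frames &
          seq_len(k) > 1L & seq_len(k) < k
        r$values[bridge] <- TRUE
        v <- inverse.rle(r)
      }
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      on <- which(r$values)
      for (j in on) {
        f0 <- starts[j]; f1 <- ends[j]
        rows[[length(rows) + 1L]] <- tibble(
          chain = res_tab$chain[ri], resnum = res_tab$resnum[ri],
          resname = res_tab$resname[ri],
          lipid_id = paste0(lip_tab$resname[li], ":", lip_tab$chain[li], ":",
                            lip_tab$resnum[li]),
          species = lip_tab$resname[li],
          t_i_ps = times[f0], t_f_ps = times[f1],
          t_res_ps = times[f1] - times[f0],
          n_frames = f1 - f0 + 1L,
          censored = f0 == 1L | f1 == nf
        )
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    chain = character(), resnum = integer(), resname = character(),
    lipid_id = character(), species = character(), t_i_ps = numeric(),
    t_f_ps = numeric(), t_res_ps = numeric(), n_frames = integer(),
    censored = logical()
  )
  attr(out, "dt") <- series$dt
  out
}

#' Summarise dwell events
#'
#' Histogram of residence times, counts of long binding events, and
#' per-residue maxima and aggregates. The aggregate residence time per
#' residue is the plain sum of its events' t_res (censored events included);
#' the mean dwell excludes censored events, whose true length is unknown.
#'
#' @param events a [dwell_events()] table.
#' @param min_event_ps duration threshold for the long-event count; events
#'   with `t_res >= min_event_ps` are counted (inclusive). Default 40 ns.
#' @param bin_width_ps histogram bin width (default 10 ns).
#' @return object of class `residence_summary`: list with `events`,
#'   `per_residue` (tibble: `chain`, `resnum`, `resname`, `n_events`,
#'   `t_res_max_ps`, `t_res_sum_ps`), `histogram` (tibble: `bin_left_ps`,
#'   `bin_right_ps`, `count`), `n_long`, `min_event_ps`, `mean_dwell_ps`.
#' @export
residence_summary <- function(events, min_event_ps = 4e4,
                              bin_width_ps = 1e4) {
  if (min_event_ps < 0) abort("`min_event_ps` must be >= 0.")
  check_scalar_number(bin_width_ps, "bin_width_ps", positive = TRUE)
  per_res <- events |>
    group_by(.data$chain, .data$resnum, .data$resname) |>
    summarise(n_events = n(),
              t_res_max_ps = max(.data$t_res_ps),
              t_res_sum_ps = sum(.data$t_res_ps), .groups = "drop")
  if (nrow(events)) {
    top_edge <- bin_width_ps * (floor(max(events$t_res_ps) / bin_width_ps) + 1L)
    breaks <- seq(0, top_edge, by = bin_width_ps)
    cnt <- graphics::hist(events$t_res_ps, breaks = breaks, plot = FALSE,
                          right = FALSE)$counts
    histo <- tibble(bin_left_ps = head(breaks, -1L),
                    bin_right_ps = breaks[-1L], count = cnt)
  } else {
    histo <- tibble(bin_left_ps = numeric(), bin_right_ps = numeric(),
                    count = integer())
  }
  uncens <- events$t_res_ps[!events$censored]
  structure(
    list(events = events, per_residue = per_res, histogram = histo,
         n_long = sum(events$t_res_ps >= min_event_ps),
         min_event_ps = min_event_ps,
         mean_dwell_ps = if (length(uncens)) mean(uncens) else NA_real_),
    class = "residence_summary"
  )
}

#' @export
print.residence_summary <- function(x, ...) {
  cat(sprintf("<residence_summary> %d events, %d with t_res >= %g ps, max t_res = %g ps\n",
              nrow(x$events), x$n_long, x$min_event_ps,
              if (nrow(x$events)) max(x$events$t_res_ps) else NA))
  invisible(x)
}

# Subsample a contact series by a frame stride.
subsample_series <- function(series, stride) {
  keep <- seq(1L, dim(series$contact)[3], by = stride)
  out <- series
  out$contact <- series$contact[, , keep, drop = FALSE]
  out$times <- series$times[keep]
  out$dt <- series$dt * stride
  out
}

#' Sensitivity of residence times to the sampling interval
#'
#' Residence-time estimates depend on the frame spacing used to detect gaps:
#' coarser sampling hides short excursions, merging events and lengthening
#' apparent dwells. This recomputes the event statistics on frame-strided
#' copies of the series (effective spacing `stride * dt`).
#'
#' @param series a [contact_series()].
#' @param strides integer vector of frame strides (>= 1).
#' @param ... passed to [dwell_events()].
#' @param min_event_ps,bin_width_ps passed to [residence_summary()].
#' @return named list of `residence_summary`, one per stride; attribute
#'   `comparison` holds a tibble (`stride`, `dt_ps`, `n_events`,
#'   `t_res_max_ps`).
#' @export
stride_sensitivity <- function(series, strides = c(1L, 5L), ...,
                               min_event_ps = 4e4, bin_width_ps = 1e4) {
  if (any(strides < 1L)) abort("Strides must be >= 1.")
  nf <- dim(series$contact)[3]
  if (any(nf %/% strides < 2L)) {
    abort("Each stride must leave >= 2 frames.")
  }
  out <- lapply(strides, function(s) {
    sub <- subsample_series(series, s)
    residence_summary(dwell_events(sub, ...), min_event_ps = min_event_ps,
                      bin_width_ps = bin_width_ps)
  })
  names(out) <- as.character(strides)
  attr(out, "comparison") <- tibble(
    stride = as.integer(strides),
    dt_ps = series$dt * strides,
    n_events = vapply(out, function(r) nrow(r$events), integer(1)),
    t_res_max_ps = vapply(out, function(r) {
      if (nrow(r$events)) max(r$events$t_res_ps) else NA_real_
    }, numeric(1))
  )
  out
}
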
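# Assembly of the labeled spectral-image datasets.
#
# DatabaseI (seizure prediction): per patient, 180 min of preictal and
# 180 min of interictal recordings, windowed at 2 s and imaged; binary
# labels with preictal positive. DatabaseII (seizure detection): per
# patient, 30 min each of interictal, PreI (earlier half of the 60-min
# preictal window), PreII (later half) and ictal recordings; four balanced
# classes.

#' Spectral-image dataset container
#'
#' @param pixels array `[S, S, 3, N]` or `NULL` when pixels were dropped
#'   after computation (metadata-only mode for full-scale counting runs)
#' @param meta data.frame with one row per image: `patient`, `class`, `y`
#'   (integer class index), `t_start_s`, `event` (source interval index)
#'   and `pix_mean` (per-image mean pixel, always retained)
#' @export
spectral_dataset <- function(pixels, meta, classes, window_s = 2) {
  structure(list(pixels = pixels, meta = meta, classes = classes,
                 window_s = window_s),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d images, classes: %s%s\n",
              nrow(x$meta), paste(x$classes, collapse = ", "),
              if (is.null(x$pixels)) " (pixels dropped)" else ""))
  print(table(x$meta$class))
  invisible(x)
}

# process one record: trim intervals of `label` to `minutes`, window, band
# power, image. Returns list(pixels or NULL, meta)
process_record <- function(rec, label, minutes, window_s, bands, layout, A,
                           out_size, keep_pixels, patient, class_name, y,
                           lowpass_hz = 30, event_offset = 0L) {
  iv <- rec$intervals[rec$intervals$label == label, , drop = FALSE]
  need <- minutes * 60
  pixels <- list(); meta <- list()
  used <- 0
  ev <- event_offset
  for (r in seq_len(nrow(iv))) {
    if (used >= need - 1e-9) break
    take <- min(iv$end_s[r] - iv$start_s[r], need - used)
    used <- used + take
    ev <- ev + 1L
    i0 <- as.integer(round(iv$start_s[r] * rec$fs))
    n <- as.integer(round(take * rec$fs))
    win <- as.integer(round(window_s * rec$fs))
    nseg <- n %/% win
    if (nseg < 1L) next
    x <- rec$data[, (i0 + 1L):(i0 + nseg * win), drop = FALSE]
    bp <- batch_band_power(x, win, rec$fs, bands, lowpass_hz = lowpass_hz)
    if (keep_pixels) {
      px <- images_from_powers(bp, out_size = out_size, layout = layout, A = A)
      pmu <- apply(px, 4, mean)
      pixels[[length(pixels) + 1L]] <- px
    } else {
      # compute images in chunks and keep only their means
      pmu <- numeric(nseg)
      step <- 1024L
      for (a in seq(1L, nseg, by = step)) {
        bsel <- a:min(a + step - 1L, nseg)
        px <- images_from_powers(bp[, , bsel, drop = FALSE],
                                 out_size = out_size, layout = layout, A = A)
        pmu[bsel] <- apply(px, 4, mean)
      }
    }
    t0 <- iv$start_s[r] + (seq_len(nseg) - 1L) * window_s
    meta[[length(meta) + 1L]] <- data.frame(
      patient = patient, class = class_name, y = y, t_start_s = t0,
      event = ev, onset_s = iv$end_s[r],
      pix_mean = pmu)
  }
  list(pixels = if (keep_pixels) pixels else NULL,
       meta = do.call(rbind, meta), events = ev - event_offset)
}

assemble_dataset <- function(chunks, classes, window_s, keep_pixels, out_size) {
  meta <- do.call(rbind, lapply(chunks, `[[`, "meta"))
  rownames(meta) <- NULL
  pixels <- NULL
  if (keep_pixels) {
    pxl <- unlist(lapply(chunks, `[[`, "pixels"), recursive = FALSE)
    ntot <- sum(vapply(pxl, function(p) dim(p)[4], 0L))
    pixels <- array(0, dim = c(out_size, out_size, 3, ntot))
    at <- 0L
    for (p in pxl) {
      k <- dim(p)[4]
      pixels[, , , at + seq_len(k)] <- p
      at <- at + k
    }
  }
  spectral_dataset(pixels, meta, classes, window_s)
}

check_supply <- function(recs, label, minutes, patient) {
  avail <- sum(vapply(recs, record_duration_s, 0, label = label))
  if (avail < minutes * 60 - 1e-6)
    stop(sprintf("patient %s: %s supplies %.1f min, needs %.0f min",
                 patient, label, avail / 60, minutes))
}

materialize <- function(pat) if (is.function(pat)) pat() else pat

#' Build the binary prediction dataset (DatabaseI)
#'
#' @param records named list, one element per patient: a list of
#'   [eeg_record()]s (or a function returning one, which is called and
#'   discarded per patient so full-scale cohorts never reside in memory at
#'   once)
#' @param minutes_per_class minutes taken per class per patient
#' @param window_s window length in seconds
#' @param keep_pixels retain the pixel array (set `FALSE` for full-scale
#'   counting runs; images are still computed, and their means kept)
#' @return a [spectral_dataset()] with classes interictal (y = 0) and
#'   preictal (y = 1, positive)
#' @export
build_database_one <- function(records, minutes_per_class = 180,
                               window_s = 2, bands = band_definitions(),
                               out_size = 64L, layout = grid_layout(),
                               keep_pixels = TRUE, verbose = FALSE) {
  A <- interp_matrix(layout$n_grid, out_size)
  chunks <- list()
  for (patient in names(records)) {
    recs <- materialize(records[[patient]])
    for (lb in c("preictal", "interictal"))
      check_supply(recs, lb, minutes_per_class, patient)
    ev <- 0L
    for (rec in recs) for (lb in c("interictal", "preictal")) {
      if (record_duration_s(rec, lb) == 0) next
      ch <- process_record(rec, lb, minutes_per_class, window_s, bands,
                           layout, A, out_size, keep_pixels, patient,
                           class_name = lb, y = as.integer(lb == "preictal"),
                           event_offset = ev)
      if (lb == "preictal") ev <- ev + ch$events
      chunks[[length(chunks) + 1L]] <- ch
    }
    rm(recs); gc(verbose = FALSE)
    if (verbose) message("processed ", patient)
  }
  assemble_dataset(chunks, c("interictal", "preictal"), window_s,
                   keep_pixels, out_size)
}

#' Build the four-class detection dataset (DatabaseII)
#'
#' The 60-min preictal window is divided into two sequential non-overlapping
#' 30-min fragments: PreI (earlier) and PreII (later). Classes are
#' interictal, PreI, PreII, ictal with `minutes_per_class` minutes per class
#' per patient, giving balanced counts by construction.
#' @inheritParams build_database_one
#' @export
build_database_two <- function(records, minutes_per_class = 30,
                               window_s = 2, bands = band_definitions(),
                               out_size = 64L, layout = grid_layout(),
                               keep_pixels = TRUE, verbose = FALSE) {
  A <- interp_matrix(layout$n_grid, out_size)
  classes <- c("interictal", "PreI", "PreII", "ictal")
  chunks <- list()
  for (patient in names(records)) {
    recs <- materialize(records[[patient]])
    check_supply(recs, "preictal", 2 * minutes_per_class, patient)
    for (lb in c("interictal", "ictal"))
      check_supply(recs, lb, minutes_per_class, patient)
    for (rec in recs) {
      for (lb in c("interictal", "ictal")) {
        if (record_duration_s(rec, lb) == 0) next
        ch <- process_record(rec, lb, minutes_per_class, window_s, bands,
                             layout, A, out_size, keep_pixels, patient,
                             class_name = lb, y = match(lb, classes) - 1L)
        chunks[[length(chunks) + 1L]] <- ch
      }
      if (record_duration_s(rec, "preictal") > 0) {
        halves <- split_preictal(rec, minutes_per_class)
        for (hn in c("PreI", "PreII")) {
          ch <- process_record(halves[[hn]], "preictal", minutes_per_class,
                               window_s, bands, layout, A, out_size,
                               keep_pixels, patient, class_name = hn,
                               y = match(hn, classes) - 1L)
          chunks[[length(chunks) + 1L]] <- ch
        }
      }
    }
    rm(recs); gc(verbose = FALSE)
    if (verbose) message("processed ", patient)
  }
  assemble_dataset(chunks, classes, window_s, keep_pixels, out_size)
}

# split the first 2*minutes of a record's preictal intervals into PreI
# (earlier half) and PreII (later half) views of the same record
split_preictal <- function(rec, minutes) {
  iv <- rec$intervals[rec$intervals$label == "preictal", , drop = FALSE]
  half <- minutes * 60
  pre1 <- rec; pre2 <- rec
  iv1 <- list(); iv2 <- list()
  for (r in seq_len(nrow(iv))) {
    s <- iv$start_s[r]; e <- iv$end_s[r]
    mid <- min(s + half, e)
    iv1[[r]] <- data.frame(start_s = s, end_s = mid, label = "preictal")
    if (e > mid)
      iv2[[r]] <- data.frame(start_s = mid, end_s = min(mid + half, e),
                             label = "preictal")
  }
  pre1$intervals <- do.call(rbind, iv1)
  pre2$intervals <- do.call(rbind, iv2)
  list(PreI = pre1, PreII = pre2)
}
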
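#' Read a recording from disk
#'
#' Dispatches on extension: `.edf` is read with the built-in EDF reader;
#' anything else is treated as a delimited channels-by-samples matrix with a
#' JSON sidecar `<path>.json` holding `fs` and `channel_names` (and
#' optionally `epochs` as a list of `[start, end)` pairs); an optional epoch
#' table `<path>.epochs.tsv` (columns `start_sample`, `end_sample`) overrides
#' the sidecar epochs.
#'
#' @param path File path.
#' @return An [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs", "channel_names"))
    if (is.null(meta[[field]]))
      stop(sprintf("sidecar %s lacks required field '%s'", sidecar, field))
  if (!is.numeric(meta$fs) || meta$fs <= 0)
    stop("sidecar fs must be a positive number")
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  if (nrow(m) != length(meta$channel_names))
    stop(sprintf("%s: %d rows but %d channel names", path, nrow(m),
                 length(meta$channel_names)))
  epochs <- NULL
  etab <- sub("(\\.[^.]+)?$", ".epochs.tsv", path)
  if (file.exists(etab)) {
    e <- read.table(etab, header = TRUE, sep = "\t")
    epochs <- cbind(start = e$start_sample, end = e$end_sample)
  } else if (!is.null(meta$epochs)) {
    ep <- meta$epochs
    if (!is.matrix(ep))
      ep <- matrix(as.integer(unlist(ep)), ncol = 2, byrow = TRUE)
    epochs <- cbind(start = as.integer(ep[, 1]), end = as.integer(ep[, 2]))
  }
  recording(m, fs = meta$fs, channel_names = meta$channel_names,
            epochs = epochs)
}

#' Write a recording as delimited matrix + JSON sidecar
#'
#' @param rec An [recording()].
#' @param path Output path for the tab-delimited matrix; `<path>.json` gets
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  write.table(format(rec$data, digits = 10, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names,
         epochs = lapply(seq_len(nrow(rec$epochs)), function(i)
           c(rec$epochs[i, "start"], rec$epochs[i, "end"]))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal EDF (European Data Format) support -------------------------
# Continuous EDF: 256-byte fixed header, 256 bytes per signal, then data
# records of 16-bit little-endian integers.  Covers the subset this package
# writes; physical unit microvolts.

edf_pad <- function(s, n) {
  s <- substr(s, 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: one data record per second (or the whole recording if
#' shorter), 16-bit samples scaled to each channel's physical range.  Epoch
#' structure is not representable in plain EDF; epochs are written alongside
#' as `<path>.epochs.tsv` and recovered by [read_edf()] when present.
#'
#' @param rec An [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  C <- nrow(data); n <- ncol(data)
  spr <- min(n, as.integer(round(rec$fs)))   # samples per record
  n_rec <- ceiling(n / spr)
  pad <- n_rec * spr - n
  if (pad > 0) data <- cbind(data, matrix(0, C, pad))
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("synthetic EEG", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (C + 1)), 8), edf_pad("", 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad(format(spr / rec$fs, digits = 8), 8),
    edf_pad(as.character(C), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width), collapse = ""), con,
              eos = NULL)
  field(rec$channel_names, 16)
  field(rep("AgAgCl electrode", C), 80)
  field(rep("uV", C), 8)
  field(format(pmin_, digits = 7), 8)
  field(format(pmax_, digits = 7), 8)
  field(rep(as.character(dmin), C), 8)
  field(rep(as.character(dmax), C), 8)
  field(rep("", C), 80)
  field(rep(as.character(spr), C), 8)
  field(rep("", C), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    block <- round((data[, idx, drop = FALSE] - pmin_) * scale + dmin)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  if (nrow(rec$epochs) > 1 || rec$epochs[1, "end"] != n ||
      rec$epochs[1, "start"] != 0) {
    write.table(data.frame(start_sample = rec$epochs[, "start"],
                           end_sample = rec$epochs[, "end"]),
                sub("(\\.[^.]+)?$", ".epochs.tsv", path),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF as written by [write_edf()] (and other
#' standard continuous EDF files with a uniform sampling rate).
#'
#' @param path EDF file path.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- rawToChar(readBin(con, "raw", 256))
  if (nchar(h) < 256) stop("corrupt EDF header: ", path)
  n_rec <- as.integer(substr(h, 237, 244))
  rec_dur <- as.numeric(substr(h, 245, 252))
  C <- as.integer(substr(h, 253, 256))
  if (is.na(C) || C < 1 || is.na(n_rec) || rec_dur <= 0)
    stop("corrupt EDF header fields in ", path)
  sh <- rawToChar(readBin(con, "raw", 256 * C))
  grab <- function(offset, width) {
    start <- offset * C
    vapply(seq_len(C), function(i)
      trimws(substr(sh, start + (i - 1) * width + 1, start + i * width)), "")
  }
  labels <- grab(0, 16)
  # byte offsets within the per-signal header block: labels 16, transducer
  # 80, unit 8, phys min 8, phys max 8, dig min 8, dig max 8, prefilter 80,
  # samples-per-record 8, reserved 32
  pmin_ <- as.numeric(grab(104, 8)); pmax_ <- as.numeric(grab(112, 8))
  dmin <- as.numeric(grab(120, 8)); dmax <- as.numeric(grab(128, 8))
  spr <- as.integer(grab(216, 8))
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported: ", path)
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * C * spr[1], size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * C * spr[1]) stop("truncated EDF data: ", path)
  data <- matrix(NA_real_, C, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1) * C * spr[1] + 1):(r * C * spr[1])],
                    nrow = spr[1], ncol = C)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(block) * scale + (pmin_ - dmin * scale)
  }
  epochs <- NULL
  etab <- sub("(\\.[^.]+)?$", ".epochs.tsv", path)
  if (file.exists(etab)) {
    e <- read.table(etab, header = TRUE, sep = "\t")
    epochs <- cbind(start = e$start_sample, end = e$end_sample)
    data <- data[, seq_len(max(e$end_sample)), drop = FALSE]
  }
  recording(data, fs = fs, channel_names = labels, epochs = epochs)
}

#' Write a simulated cohort to disk
#'
#' Exports a [simulate_cohort()] result as one EDF file per subject, a
#' demographic TSV, and a JSON ground-truth manifest (per-subject realised
#' dwell means and transition matrices plus the true label streams' run
#' lists) for use as a test oracle.
#'
#' @param cohort A [simulate_cohort()] result with rendered recordings.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (s in cohort$subjects) {
    if (is.null(s$recording))
      stop("cohort was simulated with render = 'labels'; no EEG to write")
    write_edf(s$recording, file.path(dir, paste0(s$id, ".edf")))
    ts <- attr(s$truth, "true_segments")
    manifest[[s$id]] <- list(group = s$group,
                             mean_dwell_ms = s$gt$mean_dwell,
                             transition = s$gt$transition,
                             true_classes = ts$class,
                             true_lengths = ts$length)
  }
  write.table(cohort$demographics, file.path(dir, "demographics.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export a segmentation as a tidy run list
#'
#' Writes one row per segment: subject, epoch, class, start_ms, duration_ms,
#' truncated (whether the run touches an epoch boundary).  A per-sample
#' label vector can be written alongside.
#'
#' @param seg An `ms_segmentation`.
#' @param path Output TSV path.
#' @param subject Subject identifier stored in the first column.
#' @param labels_path Optional path for the per-sample label vector (one
#'   label per line, `NA` for unassigned).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, subject = "S001",
                               labels_path = NULL) {
  s <- seg$segments
  out <- data.frame(subject = subject, epoch = s$epoch, class = s$class,
                    start_ms = s$start / seg$fs * 1000,
                    duration_ms = s$length / seg$fs * 1000,
                    truncated = s$truncated_left | s$truncated_right)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path))
    writeLines(as.character(seg$labels), labels_path)
  invisible(path)
}

# ---- template-set JSON --------------------------------------------------

#' Read / write a template set as JSON
#'
#' Serialises a [template_set()] (channel names, labels, K x C map matrix,
#' level) to JSON and back.
#'
#' @param x An `ms_templates`.
#' @param path File path.
#' @return `write_templates` returns `path` invisibly; `read_templates`
#'   returns an `ms_templates`.
#' @export
write_templates <- function(x, path) {
  jsonlite::write_json(
    list(labels = x$labels, channel_names = x$channel_names,
         level = x$level, maps = unname(t(x$maps))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("labels", "maps"))
    if (is.null(j[[f]])) stop("template JSON lacks field '", f, "'")
  template_set(t(j$maps), labels = j$labels,
               channel_names = j$channel_names,
               level = if (is.null(j$level)) "individual" else j$level)
}

# ---- tidy exports -------------------------------------------------------

#' Export cohort results as tidy TSV files
#'
#' Writes `parameters.tsv` (subject, group, class, duration_ms,
#' occurrence_per_s, coverage), `transitions.tsv` (subject, from, to,
#' probability), and `templates.json` (group template maps with channel
#' names and labels) into a directory.
#'
#' @param cohort An `ms_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$params, file.path(dir, "parameters.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  K <- cohort$K
  tr <- expand.grid(from = seq_len(K), to = seq_len(K))
  tr <- tr[tr$from != tr$to, ]
  rows <- do.call(rbind, lapply(seq_along(cohort$subject_ids), function(i)
    data.frame(subject = cohort$subject_ids[i],
               from = cohort$atlas_labels[tr$from],
               to = cohort$atlas_labels[tr$to],
               probability = cohort$transitions[, , i][as.matrix(tr)])))
  write.table(rows, file.path(dir, "transitions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(cohort$group_templates, function(t)
      list(labels = t$labels, channel_names = t$channel_names,
           maps = unname(t(t$maps)), level = t$level)),
    file.path(dir, "templates.json"), digits = NA)
  invisible(dir)
}

#' Run the full microstate pipeline from a configuration
#'
#' Thin driver over [microstate_cohort()], [ses_score()],
#' [extreme_group_split()] and [ms_group_stats()]: reads per-subject
#' recording files and a demographic TSV, runs the two-level pipeline on the
#' extreme SES groups, writes tidy results plus the resolved configuration
#' into `out_dir`, and returns the fitted objects.
#'
#' @param config Named list (or path to a JSON file) with entries
#'   `recordings` (character vector of file paths), `demographics` (TSV path
#'   with subject_id, age, gender, parent_edu_1/2, parent_occ_1/2), and
#'   optionally `band` (default c(2, 20)), `K` (default 4), `split_fraction`
#'   (default 0.27), `polarity_invariant` (default TRUE).
#' @param out_dir Output directory.
#' @return List with `cohort`, `stats`, `demographics` (scored + grouped).
#' @export
run_microstate_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("recordings", "demographics", "band", "K", "split_fraction",
             "polarity_invariant", "atlas")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(list(band = c(2, 20), K = 4, split_fraction = 0.27,
                         polarity_invariant = TRUE), config)
  if (!length(cfg$recordings)) stop("empty subject list")
  atlas <- if (!is.null(cfg$atlas)) read_templates(cfg$atlas) else NULL
  demo <- read.table(cfg$demographics, header = TRUE, sep = "\t")
  if (nrow(demo) != length(cfg$recordings))
    stop("demographics rows must match the number of recordings")
  demo <- extreme_group_split(ses_score(demo), cfg$split_fraction)
  sel <- which(demo$group != "middle")
  cohort <- microstate_cohort(cfg$recordings[sel],
                              groups = droplevels(demo$group[sel]),
                              K = cfg$K, band = cfg$band, atlas = atlas,
                              polarity_invariant = cfg$polarity_invariant,
                              subject_ids = demo$subject_id[sel])
  stats <- ms_group_stats(cohort, demo[sel, ])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_results(cohort, out_dir)
  write.table(demo, file.path(out_dir, "demographics_scored.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cfg[setdiff(names(cfg), "recordings")],
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  list(cohort = cohort, stats = stats, demographics = demo)
}
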
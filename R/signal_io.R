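# Reading and writing force-platform trials and cohort manifests.
# File dialect: comma- or tab-delimited text, one header line, UTF-8,
# decimal point. Forces in N, moments in N.m; CoP conversion to cm happens
# exactly once, inside compute_cop().

.surfaces <- c("firm", "foam")
.visions  <- c("open", "closed")

#' Construct a force-platform trial
#'
#' One 60 s quiet-stance recording of the six calibrated channels (forces
#' Fx, Fy, Fz in N; moments Mx, My, Mz in N·m) as applied by the participant
#' to the platform, together with its condition metadata.
#'
#' @param fx,fy,fz numeric force channels (N).
#' @param mx,my,mz numeric moment channels (N·m).
#' @param participant_id character scalar.
#' @param surface `"firm"` or `"foam"`.
#' @param vision `"open"` or `"closed"`.
#' @param trial_index integer 1–3.
#' @param sample_rate sampling frequency in Hz (default 100).
#' @return an object of class `force_plate_trial`.
#' @export
force_plate_trial <- function(fx, fy, fz, mx, my, mz,
                              participant_id = "P1",
                              surface = "firm", vision = "open",
                              trial_index = 1L, sample_rate = 100) {
  chans <- list(fx = fx, fy = fy, fz = fz, mx = mx, my = my, mz = mz)
  lens <- lengths(chans)
  if (any(lens < 2)) stopf("all six channels need length >= 2")
  if (length(unique(lens)) != 1) stopf("channel lengths differ: %s",
                                       paste(lens, collapse = ", "))
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stopf("sample_rate must be > 0")
  }
  surface <- match.arg(surface, .surfaces)
  vision <- match.arg(vision, .visions)
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L || trial_index > 3L) {
    stopf("trial_index must be 1, 2 or 3")
  }
  structure(
    c(lapply(chans, as.numeric),
      list(participant_id = as.character(participant_id),
           surface = surface, vision = vision,
           trial_index = trial_index, sample_rate = sample_rate)),
    class = "force_plate_trial")
}

#' @export
print.force_plate_trial <- function(x, ...) {
  cat(sprintf(
    "<force_plate_trial> %s %s/%s trial %d: %d samples @ %g Hz\n",
    x$participant_id, x$surface, x$vision, x$trial_index,
    length(x$fz), x$sample_rate))
  invisible(x)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read one force-platform trial from a delimited text file
#'
#' The file must contain the six channels in order Fx, Fy, Fz, Mx, My, Mz
#' (an optional leading time column is auto-detected by strict
#' monotonicity), with one header line.
#'
#' @param path file path.
#' @param participant_id,surface,vision,trial_index trial metadata (the file
#'   itself carries only the signals).
#' @param sample_rate sampling frequency in Hz.
#' @return a [force_plate_trial()].
#' @export
read_trial <- function(path, participant_id = "P1", surface = "firm",
                       vision = "open", trial_index = 1L,
                       sample_rate = 100) {
  if (!file.exists(path)) stopf("trial file not found: %s", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  dat <- as.data.frame(lapply(raw, function(col) {
    suppressWarnings(as.numeric(col))
  }))
  for (j in seq_along(dat)) {
    bad <- which(is.na(dat[[j]]) & !is.na(raw[[j]]) & nzchar(raw[[j]]))
    if (length(bad)) {
      stopf("non-numeric value in %s, column %d, row %d",
            path, j, bad[1] + 1L) # +1 for header line
    }
  }
  nc <- ncol(dat)
  has_time <- FALSE
  if (nc == 7L) {
    t0 <- dat[[1L]]
    if (all(diff(t0) > 0)) has_time <- TRUE
    else stopf("7 columns but first is not a monotone time axis: %s", path)
  } else if (nc != 6L) {
    stopf("expected 6 channel columns (optionally preceded by time), got %d: %s",
          nc, path)
  }
  ch <- if (has_time) dat[-1L] else dat
  force_plate_trial(ch[[1]], ch[[2]], ch[[3]], ch[[4]], ch[[5]], ch[[6]],
                    participant_id = participant_id, surface = surface,
                    vision = vision, trial_index = trial_index,
                    sample_rate = sample_rate)
}

#' Write a force-platform trial to delimited text
#'
#' Emits columns `time,fx,fy,fz,mx,my,mz` with one header line; readable by
#' [read_trial()] with channel values preserved to better than 1e-9.
#'
#' @param trial a [force_plate_trial()].
#' @param path output path.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "force_plate_trial"))
  n <- length(trial$fz)
  df <- data.frame(time = (seq_len(n) - 1) / trial$sample_rate,
                   fx = trial$fx, fy = trial$fy, fz = trial$fz,
                   mx = trial$mx, my = trial$my, mz = trial$mz)
  ok <- tryCatch({
    utils::write.table(format(df, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write trial file: %s", path)
  invisible(path)
}

#' Load a cohort of recordings from a manifest
#'
#' @param manifest path to a delimited file with columns
#'   `participant_id,surface,vision,trial,file` (trial file paths relative
#'   to the manifest's directory).
#' @param demographics path to a delimited file with columns
#'   `participant_id,age,gender,mass,height,bmi,foot_length,education_years`
#'   (gender coded `F`/`M`).
#' @param sample_rate sampling frequency of all trials (Hz).
#' @return an object of class `cohort_recordings`: a list with elements
#'   `demographics` (data frame, plus a logical `incomplete` column for
#'   participants lacking the full 4 conditions x 3 trials) and `trials`
#'   (list of [force_plate_trial()]). Participants with missing trials are
#'   flagged, never silently dropped.
#' @export
load_cohort <- function(manifest, demographics, sample_rate = 100) {
  man <- utils::read.table(manifest, header = TRUE, sep = .detect_sep(manifest),
                           stringsAsFactors = FALSE, comment.char = "#")
  dem <- utils::read.table(demographics, header = TRUE,
                           sep = .detect_sep(demographics),
                           stringsAsFactors = FALSE, comment.char = "#")
  need_m <- c("participant_id", "surface", "vision", "trial", "file")
  need_d <- c("participant_id", "age", "gender", "mass", "height", "bmi",
              "foot_length", "education_years")
  if (!all(need_m %in% names(man))) {
    stopf("manifest missing columns: %s",
          paste(setdiff(need_m, names(man)), collapse = ", "))
  }
  if (!all(need_d %in% names(dem))) {
    stopf("demographics missing columns: %s",
          paste(setdiff(need_d, names(dem)), collapse = ", "))
  }
  if (anyDuplicated(dem$participant_id)) stopf("duplicate participant ids in demographics")
  bad_s <- setdiff(unique(man$surface), .surfaces)
  if (length(bad_s)) stopf("unknown surface token: %s", bad_s[1])
  bad_v <- setdiff(unique(man$vision), .visions)
  if (length(bad_v)) stopf("unknown vision token: %s", bad_v[1])
  if (!all(man$trial %in% 1:3)) stopf("trial index outside 1..3 in manifest")
  key <- paste(man$participant_id, man$surface, man$vision, man$trial)
  if (anyDuplicated(key)) {
    stopf("duplicate trial row in manifest: %s", key[duplicated(key)][1])
  }
  if (!all(man$participant_id %in% dem$participant_id)) {
    stopf("manifest references unknown participant: %s",
          setdiff(man$participant_id, dem$participant_id)[1])
  }
  bmi_expect <- dem$mass / (dem$height / 100)^2
  off <- abs(bmi_expect - dem$bmi) > 0.5
  if (any(off)) {
    stopf("bmi inconsistent with mass/height for participant %s (off by %.2f)",
          dem$participant_id[which(off)[1]],
          max(abs(bmi_expect - dem$bmi)))
  }
  base <- dirname(manifest)
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    p <- if (file.exists(f)) f else file.path(base, f)
    trials[[i]] <- read_trial(p,
                              participant_id = man$participant_id[i],
                              surface = man$surface[i], vision = man$vision[i],
                              trial_index = man$trial[i],
                              sample_rate = sample_rate)
  }
  counts <- table(factor(man$participant_id, levels = dem$participant_id))
  dem$incomplete <- as.integer(counts[dem$participant_id]) < 12L
  structure(list(demographics = dem, trials = trials),
            class = "cohort_recordings")
}

#' @export
print.cohort_recordings <- function(x, ...) {
  cat(sprintf("<cohort_recordings> %d participants, %d trials (%d incomplete)\n",
              nrow(x$demographics), length(x$trials),
              sum(x$demographics$incomplete)))
  invisible(x)
}

#' Write a cohort to a directory as manifest + demographics + trial files
#'
#' Inverse of [load_cohort()]; lays out `demographics.csv`, `manifest.csv`
#' and one trial file per recording.
#'
#' @param cohort a `cohort_recordings` object.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_recordings"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dem <- cohort$demographics
  dem$incomplete <- NULL
  utils::write.table(dem, file.path(dir, "demographics.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  rows <- lapply(cohort$trials, function(tr) {
    fname <- sprintf("%s_%s_%s_%d.csv", tr$participant_id, tr$surface,
                     tr$vision, tr$trial_index)
    write_trial(tr, file.path(dir, fname))
    data.frame(participant_id = tr$participant_id, surface = tr$surface,
               vision = tr$vision, trial = tr$trial_index, file = fname)
  })
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(dir, "manifest.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
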
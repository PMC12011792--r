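## CSV helpers shared by feature / MI matrix writers. Matrices are printed
## with 12 significant digits (lossless round trip at that precision); lines
## starting with '#' carry provenance (config hash) and metadata.

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

write_matrix_csv <- function(mat, path, config_hash = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config: ", config_hash), con)
  if (!is.null(extra))
    for (k in names(extra))
      writeLines(paste0("# ", k, ": ", extra[[k]]), con)
  cn <- colnames(mat)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(mat)))
  rn <- rownames(mat)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(mat)))
  writeLines(paste(c("lead", cn), collapse = ","), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(rn[i], fmt12(mat[i, ])), collapse = ","), con)
  invisible(path)
}

read_matrix_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  extra <- character(0)
  for (m in meta) {
    kv <- sub("^#\\s*", "", m)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:\\s*", "", kv))
    extra[k] <- v
  }
  body <- lines[!grepl("^#", lines)]
  hdr <- strsplit(body[1], ",")[[1]]
  rows <- strsplit(body[-1], ",")
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]),
                  numeric(length(hdr) - 1)))
  rownames(mat) <- vapply(rows, `[`, "", 1)
  colnames(mat) <- hdr[-1]
  list(mat = mat, extra = extra)
}

#' Default run configuration
#'
#' One object holding every tunable of the pipeline: simulator noise,
#' preprocessing, discretization, graph threshold, classifier and evaluation
#' settings, plus the master seed. Serializes losslessly to YAML; unknown
#' keys on read are an error.
#'
#' @param noise,preprocess,discretization,gcn Component configs.
#' @param tau Adjacency threshold.
#' @param adjacency_mode `"per_record"` or `"cohort"`.
#' @param n_subjects,recordings_per_subject,duration,fs Simulator shape.
#' @param K Fold count for k-fold cross-validation.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(noise = noise_spec(),
                       preprocess = preprocess_config(),
                       discretization = discretization_config(),
                       gcn = gcn_config(),
                       tau = 0, adjacency_mode = "per_record",
                       n_subjects = 20, recordings_per_subject = 6,
                       duration = 10, fs = 257, K = 10, seed = 42) {
  structure(list(noise = noise, preprocess = preprocess,
                 discretization = discretization, gcn = gcn,
                 tau = as.numeric(tau),
                 adjacency_mode = adjacency_mode,
                 n_subjects = as.integer(n_subjects),
                 recordings_per_subject = as.integer(recordings_per_subject),
                 duration = as.numeric(duration), fs = as.numeric(fs),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "run_config")
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Serialize / load a run configuration (YAML)
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(strip_class(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config` returns a `run_config`; unknown keys error.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- run_config()
  check_keys <- function(got, ref, where) {
    unknown <- setdiff(names(got), names(ref))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(raw, def, "run_config")
  for (sub in c("noise", "preprocess", "discretization", "gcn"))
    if (!is.null(raw[[sub]])) check_keys(raw[[sub]], def[[sub]], sub)
  merged <- utils::modifyList(strip_class(unclass(def)), raw)
  pre <- merged$preprocess
  pre$feature_mode <- match.arg(pre$feature_mode, c("raw", "wavelet"))
  dc <- merged$discretization
  gc <- merged$gcn[setdiff(names(merged$gcn), "batch_size")]
  gcn <- do.call(gcn_config, gc)
  if (!is.null(merged$gcn$batch_size))
    gcn$batch_size <- merged$gcn$batch_size
  run_config(noise = do.call(noise_spec, merged$noise),
             preprocess = do.call(preprocess_config, pre),
             discretization = discretization_config(dc$n_bins, dc$strategy),
             gcn = gcn, tau = merged$tau,
             adjacency_mode = merged$adjacency_mode,
             n_subjects = merged$n_subjects,
             recordings_per_subject = merged$recordings_per_subject,
             duration = merged$duration, fs = merged$fs, K = merged$K,
             seed = merged$seed)
}

#' Provenance hash of a configuration object
#' @param cfg Any R object (normally a `run_config`).
#' @return Short hex digest string.
#' @export
config_hash <- function(cfg) {
  digest::digest(strip_class(unclass(cfg)), algo = "sha1")
}

## ---- WFDB record I/O (format 16) ----

parse_gain <- function(tok) {
  # forms: "200", "200(0)", "200(0)/mV"
  tok <- sub("/.*$", "", tok)
  baseline <- 0
  m <- regmatches(tok, regexec("^([-0-9.eE+]+)\\(([-0-9]+)\\)$", tok))[[1]]
  if (length(m) == 3) {
    gain <- as.numeric(m[2]); baseline <- as.numeric(m[3])
  } else gain <- as.numeric(tok)
  if (is.na(gain) || gain == 0) gain <- 200
  c(gain = gain, baseline = baseline)
}

#' Read a WFDB record (format 16) as an `ecg_recording`
#'
#' Parses the plain-text header (`<prefix>.hea`) and decodes the 16-bit
#' little-endian two's-complement signal file to millivolts via each
#' channel's gain and baseline. Lead order is taken from the header labels,
#' mapped to the canonical I, II, III, aVR, aVL, aVF, V1--V6 order when all
#' twelve are present.
#'
#' @param path_prefix Record path without extension.
#' @param window Optional `c(start_s, length_s)` sub-window to extract.
#' @param subject_id Optional label; defaults to a `subject` comment in the
#'   header, else the record name.
#' @return An `ecg_recording`.
#' @export
read_wfdb_record <- function(path_prefix, window = NULL, subject_id = NULL) {
  hea <- paste0(path_prefix, ".hea")
  if (!file.exists(hea)) stop("missing header file: ", hea)
  lines <- readLines(hea)
  comments <- grep("^#", lines, value = TRUE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  if (nsig != 12)
    stop("expected 12 signal channels, header declares ", nsig)
  sig_lines <- lines[2:(1 + nsig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  dat_file <- fields[[1]][1]
  fmt <- sub("x.*$", "", fields[[1]][2])
  if (fmt != "16")
    stop("unsupported WFDB sample format: ", fields[[1]][2])
  gb <- t(vapply(fields, function(f) parse_gain(f[3]), c(gain = 0,
                                                         baseline = 0)))
  labels <- vapply(fields, function(f) {
    if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  }, "")
  dat_path <- file.path(dirname(path_prefix), dat_file)
  raw_n <- file.info(dat_path)$size / 2
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2,
                  endian = "little", signed = TRUE)
  nsamp <- length(vals) %/% nsig
  m <- matrix(vals[seq_len(nsamp * nsig)], nrow = nsig)   # ch-major frames
  sig <- (m - gb[, "baseline"]) / gb[, "gain"]
  if (!is.null(window)) {
    i0 <- max(1L, round(window[1] * fs) + 1L)
    i1 <- min(ncol(sig), i0 + round(window[2] * fs) - 1L)
    sig <- sig[, i0:i1, drop = FALSE]
  }
  # map to canonical order when the full 12-lead set is present
  labs <- trimws(labels)
  canon <- toupper(LEAD_NAMES)
  if (setequal(toupper(labs), canon)) {
    ord <- match(canon, toupper(labs))
    sig <- sig[ord, , drop = FALSE]
    labs <- LEAD_NAMES
  }
  rownames(sig) <- labs
  if (is.null(subject_id)) {
    sc <- grep("subject", comments, value = TRUE, ignore.case = TRUE)
    subject_id <- if (length(sc))
      trimws(sub(".*subject[: ]*", "", sc[1], ignore.case = TRUE))
    else rec_name
  }
  structure(list(record_id = rec_name, subject_id = subject_id, fs = fs,
                 signal = sig, lead_names = labs),
            class = "ecg_recording")
}

#' Write an `ecg_recording` as a WFDB format-16 record
#'
#' @param recording An `ecg_recording`.
#' @param dir Output directory.
#' @param gain ADC units per mV (default 200).
#' @return The record path prefix, invisibly.
#' @export
write_wfdb_record <- function(recording, dir, gain = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- recording$record_id
  sig <- recording$signal
  nsig <- nrow(sig); nsamp <- ncol(sig)
  adc <- round(sig * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  hdr <- c(sprintf("%s %d %g %d", rec, nsig, recording$fs, nsamp),
           sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 %s", rec, gain,
                   recording$lead_names),
           sprintf("# subject: %s", recording$subject_id))
  writeLines(hdr, file.path(dir, paste0(rec, ".hea")))
  con <- file(file.path(dir, paste0(rec, ".dat")), "wb")
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  close(con)
  invisible(file.path(dir, rec))
}

#' Write a synthetic cohort as WFDB records plus a manifest CSV
#'
#' @param cohort List of `ecg_recording`.
#' @param dir Output directory.
#' @param config_hash Optional provenance string for the manifest.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort_wfdb <- function(cohort, dir, config_hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(cohort, function(r) {
    write_wfdb_record(r, dir)
    sprintf("%s,%s,%s", r$record_id, r$subject_id,
            paste0(r$record_id))
  }, "")
  manifest <- file.path(dir, "manifest.csv")
  hdr <- "record_id,subject_id,path"
  pre <- if (!is.null(config_hash)) paste0("# config: ", config_hash)
  writeLines(c(pre, hdr, rows), manifest)
  invisible(manifest)
}

#' Read a cohort manifest and its records
#' @param manifest Path to a manifest CSV written by [write_cohort_wfdb()].
#' @return List of `ecg_recording`.
#' @export
read_cohort_wfdb <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest)
  lines <- lines[!grepl("^#", lines)][-1]
  lapply(lines, function(ln) {
    f <- strsplit(ln, ",")[[1]]
    read_wfdb_record(file.path(dir, f[3]), subject_id = f[2])
  })
}
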
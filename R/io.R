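VOLTAGE_SCHEMA_VERSION <- 1L

#' Write a set of voltage recordings to a binary + JSON-sidecar store
#'
#' One little-endian float64 file per electrode plus a `manifest.json`
#' sidecar holding, for every dataset, the metadata required to reconstruct
#' it (sampling rate, well, electrode, div, genotype, batch, sample count)
#' and a schema version.
#'
#' @param recs list of [voltage_recording()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_voltage_store <- function(recs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    file <- sprintf("trace_%04d.bin", i)
    con <- file(file.path(path, file), "wb")
    writeBin(r$samples, con, size = 8, endian = "little")
    close(con)
    list(file = file, sampling_rate = r$sampling_rate, well = r$well,
         electrode = r$electrode, div = r$div, genotype = r$genotype,
         batch = r$batch, n_samples = length(r$samples))
  })
  jsonlite::write_json(list(schema_version = VOLTAGE_SCHEMA_VERSION,
                            records = records),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a voltage store written by [write_voltage_store()]
#'
#' Validates the schema version, the presence of required metadata for every
#' dataset, and that each binary file holds exactly the declared number of
#' samples.
#'
#' @param path store directory.
#' @return list of [voltage_recording()].
#' @export
read_voltage_store <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  stop_if_not(file.exists(mf_path), sprintf("no manifest.json under %s", path))
  mf <- jsonlite::read_json(mf_path)
  stop_if_not(identical(as.integer(mf$schema_version %||% -1L),
                        VOLTAGE_SCHEMA_VERSION),
              "unsupported voltage store schema version")
  required <- c("file", "sampling_rate", "well", "electrode", "div")
  lapply(mf$records, function(rec) {
    missing <- setdiff(required, names(rec))
    if (length(missing)) {
      stop(sprintf("dataset '%s': missing attribute(s) %s",
                   rec$file %||% "<unnamed>",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    f <- file.path(path, rec$file)
    stop_if_not(file.exists(f), sprintf("dataset file missing: %s", rec$file))
    n_expect <- as.integer(rec$n_samples)
    info <- file.info(f)
    if (info$size != 8 * n_expect) {
      stop(sprintf("dataset '%s': truncated (%d bytes, expected %d)",
                   rec$file, info$size, 8 * n_expect), call. = FALSE)
    }
    con <- file(f, "rb")
    x <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
    close(con)
    voltage_recording(x, rec$sampling_rate, well = rec$well,
                      electrode = rec$electrode, div = rec$div,
                      genotype = rec$genotype %||% NA_character_,
                      batch = rec$batch %||% NA_character_)
  })
}

#' Write spike trains as tidy CSV
#'
#' Columns: `well`, `electrode`, `div`, `genotype`, `batch`, `time`,
#' `amplitude`. Times are seconds from recording start.
#'
#' @param trains list of [spike_train()].
#' @param path output CSV file.
#' @param duration recorded alongside in a `duration` column (taken from the
#'   trains).
#' @export
write_spike_csv <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(well = tr$well, electrode = tr$electrode, div = tr$div,
               genotype = tr$genotype, batch = tr$batch,
               duration = tr$duration, time = tr$times,
               amplitude = tr$amplitudes)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read spike trains from tidy CSV
#'
#' @param path CSV written by [write_spike_csv()].
#' @return list of [spike_train()], one per well/electrode/div combination.
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well", "electrode", "div", "duration", "time")
  missing <- setdiff(need, names(df))
  stop_if_not(!length(missing),
              sprintf("spike CSV missing column(s): %s",
                      paste(missing, collapse = ", ")))
  key <- paste(df$div, df$well, df$electrode, sep = "|")
  lapply(split(seq_len(nrow(df)), key), function(ix) {
    d <- df[ix, ]
    d <- d[order(d$time), ]
    spike_train(d$time, d$amplitude, duration = d$duration[1],
                well = d$well[1], electrode = d$electrode[1], div = d$div[1],
                genotype = as.character(d$genotype[1] %||% NA),
                batch = as.character(d$batch[1] %||% NA))
  })
}

#' Run the full MEA analysis pipeline
#'
#' Simulates (or loads) recordings, optionally renders and detects spikes
#' from voltage, detects bursts and network bursts, computes well features,
#' and writes the outputs (features CSV, raster CSV of per-electrode spike
#' times, run manifest) into an output directory. Deterministic for a given
#' seed.
#'
#' @param config list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{profile}{shipped profile id, profile JSON path, or anchor table}
#'     \item{wells, divs, duration}{plate settings (defaults 8, 4:42, 300)}
#'     \item{level}{`"train"` (default) to analyze ground-truth spike trains
#'       directly, or `"voltage"` to render voltage and run spike detection}
#'     \item{spike_csv}{optional path to a spike-train CSV; skips simulation
#'       and detection entirely}
#'     \item{noise_sd, sampling_rate}{voltage rendering settings}
#'     \item{seed}{master seed}
#'     \item{out_dir}{output directory}
#'   }
#' @return Invisibly, a list with the features table and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  if (!is.null(config$spike_csv)) {
    trains <- read_spike_csv(config$spike_csv)
  } else {
    profile <- make_profile(config$profile %||% "corrected")
    plate <- plate_spec(n_wells = config$wells %||% 8L,
                        duration = config$duration %||% 300,
                        sampling_rate = config$sampling_rate %||% 20000,
                        divs = config$divs %||% 4:42)
    sim <- simulate_spike_trains(profile, plate, seed = seed)
    trains <- sim$trains
    if (identical(config$level %||% "train", "voltage")) {
      det <- detection_params()
      sub_seeds <- derive_seeds(seed, length(trains), salt = 77L)
      trains <- lapply(seq_along(trains), function(i) {
        rec <- render_voltage(trains[[i]], noise_sd = config$noise_sd %||% 8,
                              sampling_rate = plate$sampling_rate,
                              seed = sub_seeds[i])
        detect_spikes(rec, det)
      })
    }
  }
  feats <- mea_features(trains)
  feats_path <- file.path(out_dir, "features.csv")
  utils::write.csv(feats, feats_path, row.names = FALSE, na = "")
  raster_path <- file.path(out_dir, "raster.csv")
  write_spike_csv(trains, raster_path)
  inactive <- setdiff(
    unique(vapply(trains, function(tr) paste0("div", tr$div, ":well", tr$well),
                  character(1))),
    paste0("div", feats$div, ":well", feats$well))
  if (length(inactive)) {
    message("excluded inactive wells: ", paste(inactive, collapse = ", "))
  }
  manifest <- list(seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("meadev")),
                   n_trains = length(trains),
                   n_feature_rows = nrow(feats) %||% 0L,
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(features = feats, paths = list(
    features = feats_path, raster = raster_path,
    manifest = file.path(out_dir, "manifest.json"))))
}
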
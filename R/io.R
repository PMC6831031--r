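#' Read and write footprint lane profiles
#'
#' Lane profiles live one CSV per lane (`base_index,intensity`) next to a
#' `manifest.csv` (`replicate,file,is_control`) naming the replicates and
#' the control lane; a `truth.json` sidecar is written for simulated data.
#'
#' @param lanes Lane tibble (`replicate`, `base_index`, `intensity`,
#'   `is_control`).
#' @param dir Directory holding (or to hold) the lane CSVs and manifest.
#' @return `read_profiles()` returns the lane tibble (with any truth
#'   record reattached); `write_profiles()` returns `dir` invisibly.
#' @export
write_profiles <- function(lanes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lanes |>
    dplyr::distinct(.data$replicate, .data$is_control) |>
    dplyr::mutate(file = paste0(.data$replicate, ".csv"))
  purrr::pwalk(manifest, function(replicate, is_control, file) {
    df <- dplyr::filter(lanes, .data$replicate == !!replicate)
    utils::write.csv(df[, c("base_index", "intensity")],
                     file.path(dir, file), row.names = FALSE)
  })
  utils::write.csv(manifest[, c("replicate", "file", "is_control")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- get_truth(lanes)
  if (!is.null(truth)) write_truth_record(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- read_checked_csv(mpath, c(replicate = "character",
                                        file = "character",
                                        is_control = "logical"))
  if (sum(manifest$is_control) != 1) {
    stop("manifest must name exactly one control lane (found ",
         sum(manifest$is_control), ")", call. = FALSE)
  }
  lanes <- purrr::pmap_dfr(manifest, function(replicate, file, is_control) {
    df <- read_checked_csv(file.path(dir, file),
                           c(base_index = "numeric", intensity = "numeric"))
    if (any(df$intensity < 0)) {
      stop("negative intensity in ", file, " (line ",
           which(df$intensity < 0)[1] + 1, ")", call. = FALSE)
    }
    dplyr::mutate(df, replicate = replicate, is_control = is_control)
  })
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) lanes <- set_truth(lanes, read_truth_record(tpath))
  lanes
}

#' Read and write unwinding band time courses
#'
#' CSV dialect `time_min,Is,Id,row_type`, with `row_type` in `obs`, `zero`,
#' `boiled`; exactly one zero-time and one boiled row are required and the
#' observation times must be strictly increasing.
#'
#' @param tc Band time-course tibble.
#' @param path CSV path; for simulated data a `<path>.truth.json` sidecar
#'   is written.
#' @return `read_timecourse()` returns the validated tibble.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(tc[, c("time_min", "Is", "Id", "row_type")], path,
                   row.names = FALSE)
  truth <- get_truth(tc)
  if (!is.null(truth)) write_truth_record(truth, paste0(path, ".truth.json"))
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tc <- read_checked_csv(path, c(time_min = "numeric", Is = "numeric",
                                 Id = "numeric", row_type = "character"),
                         na_ok = "time_min")
  bad <- which(!tc$row_type %in% c("obs", "zero", "boiled"))
  if (length(bad)) {
    stop("invalid row_type '", tc$row_type[bad[1]], "' at line ", bad[1] + 1,
         " of ", path, call. = FALSE)
  }
  if (sum(tc$row_type == "zero") != 1 || sum(tc$row_type == "boiled") != 1) {
    stop("time course must contain exactly one zero and one boiled row: ",
         path, call. = FALSE)
  }
  tt <- tc$time_min[tc$row_type %in% c("zero", "obs")]
  if (anyNA(tt) || any(diff(tt) <= 0)) {
    stop("observation times must be present and strictly increasing: ", path,
         call. = FALSE)
  }
  if (any(c(tc$Is, tc$Id) < 0)) {
    stop("band intensities must be non-negative: ", path, call. = FALSE)
  }
  tpath <- paste0(path, ".truth.json")
  if (file.exists(tpath)) tc <- set_truth(tc, read_truth_record(tpath))
  tibble::as_tibble(tc)
}

#' Read and write anisotropy titrations
#'
#' CSV dialect `conc_nM,anisotropy` with strictly increasing
#' concentrations.
#' @param series Titration tibble.
#' @param path CSV path.
#' @return `read_titration()` returns the validated tibble.
#' @export
write_titration <- function(series, path) {
  utils::write.csv(series[, c("conc_nM", "anisotropy")], path,
                   row.names = FALSE)
  truth <- get_truth(series)
  if (!is.null(truth)) write_truth_record(truth, paste0(path, ".truth.json"))
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  ser <- read_checked_csv(path, c(conc_nM = "numeric", anisotropy = "numeric"))
  if (any(ser$conc_nM < 0) || any(diff(ser$conc_nM) <= 0)) {
    stop("concentrations must be non-negative and strictly increasing: ",
         path, call. = FALSE)
  }
  tpath <- paste0(path, ".truth.json")
  if (file.exists(tpath)) ser <- set_truth(ser, read_truth_record(tpath))
  ser
}

#' Read and write stopped-flow traces
#'
#' CSV dialect `time_s,signal,segment` preceded by a commented condition
#' header block (`# label_site: ...` etc.); time must be strictly
#' increasing within and across segments.
#'
#' @param trace Trace tibble with a `condition` attribute.
#' @param path CSV path.
#' @return `read_trace()` returns the validated tibble with its condition
#'   reattached.
#' @export
write_trace <- function(trace, path) {
  cond <- attr(trace, "condition")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cond)) {
    writeLines(sprintf("# %s: %s",
                       c("label_site", "block", "substrate_class", "atp"),
                       unlist(cond[c("label_site", "block",
                                     "substrate_class", "atp")])), con)
  }
  utils::write.csv(trace[, c("time_s", "signal", "segment")], con,
                   row.names = FALSE)
  truth <- get_truth(trace)
  if (!is.null(truth)) write_truth_record(truth, paste0(path, ".truth.json"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  cond <- NULL
  if (length(hdr)) {
    kv <- strsplit(sub("^#\\s*", "", lines[hdr]), ":\\s*")
    vals <- stats::setNames(purrr::map_chr(kv, 2), purrr::map_chr(kv, 1))
    cond <- condition_descriptor(
      label_site = vals[["label_site"]], block = vals[["block"]],
      substrate_class = vals[["substrate_class"]], atp = vals[["atp"]]
    )
  }
  trace <- read_checked_csv(path, c(time_s = "numeric", signal = "numeric",
                                    segment = "numeric"),
                            comment = "#")
  bad <- which(diff(trace$time_s) <= 0)
  if (length(bad)) {
    stop("non-monotone time at data line ", bad[1] + 1, " of ", path,
         call. = FALSE)
  }
  if (any(diff(trace$segment) < 0)) {
    stop("segment ids must be non-decreasing: ", path, call. = FALSE)
  }
  attr(trace, "condition") <- cond
  tpath <- paste0(path, ".truth.json")
  if (file.exists(tpath)) trace <- set_truth(trace, read_truth_record(tpath))
  trace
}

# Strict CSV reader: fixed header, typed columns, line-numbered errors.
read_checked_csv <- function(path, cols, na_ok = character(), comment = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = comment)
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  for (nm in names(cols)) {
    v <- df[[nm]]
    if (cols[[nm]] == "numeric") {
      v <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v) & !(nm %in% na_ok & is.na(df[[nm]])))
      bad <- bad[!is.na(df[[nm]][bad]) | !(nm %in% na_ok)]
      if (length(bad)) {
        stop("non-numeric value '", df[[nm]][bad[1]], "' in column ", nm,
             " at line ", bad[1] + 1, " of ", path, call. = FALSE)
      }
      df[[nm]] <- v
    } else if (cols[[nm]] == "logical") {
      df[[nm]] <- as.logical(v)
      if (anyNA(df[[nm]])) {
        stop("non-logical value in column ", nm, " of ", path, call. = FALSE)
      }
    } else {
      df[[nm]] <- as.character(v)
    }
  }
  tibble::as_tibble(df[, names(cols)])
}

#' Serialize and restore a truth record
#'
#' Every simulated dataset's generating parameters round-trip through a
#' JSON sidecar so provenance survives the writers/readers.
#' @param truth A [truth_record()].
#' @param path JSON path.
#' @return `read_truth_record()` returns the [truth_record()].
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  pop <- truth$population
  obj <- list(
    population = if (!is.null(pop)) {
      list(probs = as.list(stats::setNames(
        pop$probs$prob, paste(pop$probs$arm, pop$probs$orientation, sep = "."))),
        unbound = pop$unbound)
    },
    productive_rule = truth$productive_rule,
    kinetics = truth$kinetics,
    seed = truth$seed,
    extra = truth$extra
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pop <- NULL
  if (!is.null(obj$population)) {
    p <- obj$population$probs
    pop <- binding_population(
      arm3_N = p[["arm3.N_at_duplex"]], arm3_C = p[["arm3.C_at_duplex"]],
      arm5_N = p[["arm5.N_at_duplex"]], arm5_C = p[["arm5.C_at_duplex"]],
      unbound = obj$population$unbound
    )
  }
  tr <- truth_record(
    population = pop,
    productive_rule = obj$productive_rule,
    kinetics = as.list(obj$kinetics),
    seed = obj$seed
  )
  tr$extra <- as.list(obj$extra)
  tr
}

#' Load a run configuration
#'
#' YAML key/value configuration for a pipeline run. Known keys: `substrate`
#' (preset name or inline geometry block), `regions` (`n_region`,
#' `c_region`, `coordinate_origin`), `seed`, `noise_cv`, `noise_sd`,
#' `n_replicates`, `truth_direction`, `fit` (options), `output_dir`.
#' Unknown keys are rejected; a `seed` is mandatory whenever the config
#' requests simulation.
#'
#' @param path YAML path.
#' @return Named list with a parsed `substrate` and `regions` where given.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("substrate", "regions", "seed", "noise_cv", "noise_sd",
             "n_replicates", "truth_direction", "fit", "output_dir",
             "simulate")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(cfg$simulate) && is.null(cfg$seed)) {
    stop("config requests simulation but provides no seed", call. = FALSE)
  }
  if (!is.null(cfg$substrate)) {
    cfg$substrate <- if (is.character(cfg$substrate)) {
      substrate_preset(cfg$substrate)
    } else {
      substrate_from_list(cfg$substrate$name %||% "custom", cfg$substrate)
    }
  }
  if (!is.null(cfg$regions)) {
    strand_len <- cfg$regions$strand_len %||%
      (if (!is.null(cfg$substrate)) cfg$substrate$labelled_strand_len else
        stop("regions override needs strand_len or a substrate", call. = FALSE))
    cfg$regions <- region_map(
      unlist(cfg$regions$n_region), unlist(cfg$regions$c_region),
      cfg$regions$coordinate_origin %||% "from_5prime", strand_len
    )
  }
  cfg
}
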
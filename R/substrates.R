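#' Define a fork or tailed DNA substrate
#'
#' A fork substrate is a duplex flanked by two single-stranded arms: the
#' 3'-arm is the tail of the strand the hexamer encircles (the translocating
#' strand, entered 3'->5'), the 5'-arm the tail of the excluded strand. Only
#' geometry matters downstream -- lengths, which strand carries the
#' fluorophore label, and optional marker positions (biotin/streptavidin
#' block, FAM reporter). Sequences are never modelled.
#'
#' @param name Identifier for the substrate.
#' @param duplex_len Duplex length in bp.
#' @param arm3_len Length (nt) of the single-stranded 3'-arm (on the
#'   encircled strand).
#' @param arm5_len Length (nt) of the single-stranded 5'-arm (on the
#'   excluded strand).
#' @param labelled_strand Which strand carries the fluorophore:
#'   `"encircled_3arm"` or `"excluded_5arm"`.
#' @param label_end Which duplex end carries the label, `"duplex_5prime"` or
#'   `"duplex_3prime"`. The encircled strand presents its 5' end at the
#'   duplex; the excluded strand its 3' end.
#' @param block_pos Optional biotin/streptavidin block position, nt from the
#'   duplex junction along the encircled strand's arm.
#' @param reporter_pos Optional FAM reporter position, nt from the duplex
#'   junction along the excluded strand.
#' @return An object of class `fork_substrate` (a named list).
#' @examples
#' fork_substrate("equal_arm", duplex_len = 20, arm3_len = 30, arm5_len = 30)
#' @export
fork_substrate <- function(name,
                           duplex_len,
                           arm3_len,
                           arm5_len,
                           labelled_strand = c("encircled_3arm", "excluded_5arm"),
                           label_end = NULL,
                           block_pos = NULL,
                           reporter_pos = NULL) {
  labelled_strand <- match.arg(labelled_strand)
  if (is.null(label_end)) {
    # the encircled strand's duplex end is its 5' terminus, the excluded
    # strand's is its 3' terminus
    label_end <- if (labelled_strand == "encircled_3arm") "duplex_5prime" else "duplex_3prime"
  }
  label_end <- match.arg(label_end, c("duplex_5prime", "duplex_3prime"))

  for (len in c(duplex_len = duplex_len, arm3_len = arm3_len, arm5_len = arm5_len)) {
    if (!is.numeric(len) || length(len) != 1 || is.na(len) || len < 0 || len != round(len)) {
      stop("substrate lengths must be single non-negative integers; got ",
           paste(names(len), "=", len), call. = FALSE)
    }
  }
  consistent <- (labelled_strand == "encircled_3arm" && label_end == "duplex_5prime") ||
    (labelled_strand == "excluded_5arm" && label_end == "duplex_3prime")
  if (!consistent) {
    stop("label_end '", label_end, "' is inconsistent with labelled_strand '",
         labelled_strand, "': the encircled strand is labelled at its 5' duplex end, ",
         "the excluded strand at its 3' duplex end", call. = FALSE)
  }

  arm_len <- if (labelled_strand == "encircled_3arm") arm3_len else arm5_len
  strand_len <- duplex_len + arm_len
  if (!is.null(block_pos) && (block_pos < 0 || block_pos > arm3_len)) {
    stop("block_pos must lie within the encircled strand's 3'-arm (0..",
         arm3_len, ")", call. = FALSE)
  }
  if (!is.null(reporter_pos) && (reporter_pos < 0 || reporter_pos > arm5_len)) {
    stop("reporter_pos must lie within the excluded strand's 5'-arm (0..",
         arm5_len, ")", call. = FALSE)
  }

  structure(
    list(
      name = as.character(name),
      duplex_len = as.integer(duplex_len),
      arm3_len = as.integer(arm3_len),
      arm5_len = as.integer(arm5_len),
      labelled_strand = labelled_strand,
      label_end = label_end,
      labelled_strand_len = as.integer(strand_len),
      block_pos = block_pos,
      reporter_pos = reporter_pos
    ),
    class = "fork_substrate"
  )
}

#' @export
print.fork_substrate <- function(x, ...) {
  cat("<fork_substrate> ", x$name, "\n",
      "  duplex ", x$duplex_len, " bp; 3'-arm ", x$arm3_len,
      " nt; 5'-arm ", x$arm5_len, " nt\n",
      "  labelled strand: ", x$labelled_strand, " (", x$labelled_strand_len,
      " nt, label at ", x$label_end, ")\n", sep = "")
  invisible(x)
}

#' Region map: which bases report which binding orientation
#'
#' Footprint quantification attributes cleavage in a junction-proximal
#' interval of the single-stranded window to hexamers bound N-face-at-duplex
#' (N@duplex) and cleavage in the junction-distal interval to C@duplex.
#' Coordinates are 1-based inclusive, counted from the end named in
#' `coordinate_origin` (the convention switches between substrates, so it is
#' carried on the object rather than assumed).
#'
#' @param n_region Integer length-2 vector, inclusive base interval
#'   attributed to N@duplex.
#' @param c_region Interval attributed to C@duplex.
#' @param coordinate_origin `"from_5prime"` or `"from_3prime"` of the
#'   labelled strand.
#' @param strand_len Length of the labelled strand the map applies to.
#' @return A `region_map` object.
#' @export
region_map <- function(n_region, c_region,
                       coordinate_origin = c("from_5prime", "from_3prime"),
                       strand_len) {
  coordinate_origin <- match.arg(coordinate_origin)
  chk <- function(r, nm) {
    if (length(r) != 2 || any(r != round(r)) || r[1] > r[2] || r[1] < 1) {
      stop(nm, " must be an increasing 1-based inclusive interval", call. = FALSE)
    }
    if (r[2] > strand_len) {
      stop(nm, " extends past the labelled strand (length ", strand_len, ")",
           call. = FALSE)
    }
    as.integer(r)
  }
  n_region <- chk(n_region, "n_region")
  c_region <- chk(c_region, "c_region")
  if (max(n_region[1], c_region[1]) <= min(n_region[2], c_region[2])) {
    stop("n_region and c_region overlap", call. = FALSE)
  }
  structure(
    list(n_region = n_region, c_region = c_region,
         coordinate_origin = coordinate_origin,
         strand_len = as.integer(strand_len)),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> N@duplex: [", x$n_region[1], ",", x$n_region[2],
      "]  C@duplex: [", x$c_region[1], ",", x$c_region[2], "]  (",
      x$coordinate_origin, ", strand ", x$strand_len, " nt)\n", sep = "")
  invisible(x)
}

#' Default region map for a substrate
#'
#' For labelled strands of at least 50 nt (the standard 20-bp-duplex,
#' 30-nt-arm designs) the fixed intervals bases 20-35 (N@duplex) and 36-50
#' (C@duplex) are used, counted from the labelled (duplex) end: from the
#' 5'-end for the encircled-strand (Cy3) substrates and from the 3'-end for
#' the excluded-strand (Cy5) substrates. Shorter strands split the
#' single-stranded window at its midpoint.
#'
#' @param substrate A [fork_substrate()].
#' @return A [region_map()].
#' @export
default_region_map <- function(substrate) {
  stopifnot(inherits(substrate, "fork_substrate"))
  origin <- if (substrate$labelled_strand == "encircled_3arm") "from_5prime" else "from_3prime"
  L <- substrate$labelled_strand_len
  if (L >= 50) {
    return(region_map(c(20L, 35L), c(36L, 50L), origin, strand_len = L))
  }
  # single-strand window: bases beyond the duplex, counted from the label end
  win <- c(substrate$duplex_len + 1L, L)
  if (diff(win) + 1L < 2L) {
    stop("single-strand window shorter than 2 bases; cannot build a region map",
         call. = FALSE)
  }
  mid <- win[1] + (win[2] - win[1] + 1L) %/% 2L - 1L
  region_map(c(win[1], mid), c(mid + 1L, win[2]), origin, strand_len = L)
}

#' Single-strand quantification window of a substrate
#'
#' The base interval (in the labelled strand's coordinates, counted from the
#' labelled end) covered by the two orientation regions.
#' @param regions A [region_map()].
#' @return Integer length-2 vector.
#' @export
ss_window <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  c(min(regions$n_region[1], regions$c_region[1]),
    max(regions$n_region[2], regions$c_region[2]))
}

#' Named substrate presets
#'
#' The four fork designs used throughout: equal arms (30/30 nt around a
#' 20-bp duplex), 3'-long arm (30-nt 3'-arm, 8-nt 5'-arm), 5'-long arm
#' (8-nt 3'-arm, 30-nt 5'-arm), and the stopped-flow fork with a 7-nt 5'-arm
#' plus a streptavidin block on the 3'-arm. Definitions live in a YAML file
#' under `inst/extdata/` and can be extended via [read_substrate_config()].
#'
#' @param name Preset name; see `substrate_presets()` for the list.
#' @return A [fork_substrate()] (or for `substrate_presets()`, a character
#'   vector of available names).
#' @export
substrate_preset <- function(name) {
  cfg <- yaml::read_yaml(system.file("extdata", "substrates.yaml",
                                     package = "mcmorient"))
  if (!name %in% names(cfg)) {
    stop("unknown substrate preset '", name, "'; available: ",
         paste(names(cfg), collapse = ", "), call. = FALSE)
  }
  substrate_from_list(name, cfg[[name]])
}

#' @rdname substrate_preset
#' @export
substrate_presets <- function() {
  names(yaml::read_yaml(system.file("extdata", "substrates.yaml",
                                    package = "mcmorient")))
}

substrate_from_list <- function(name, x) {
  known <- c("duplex_len", "arm3_len", "arm5_len", "labelled_strand",
             "label_end", "block_pos", "reporter_pos")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown substrate config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  fork_substrate(
    name,
    duplex_len = x$duplex_len, arm3_len = x$arm3_len, arm5_len = x$arm5_len,
    labelled_strand = x$labelled_strand %||% "encircled_3arm",
    label_end = x$label_end,
    block_pos = x$block_pos, reporter_pos = x$reporter_pos
  )
}

#' Load substrate definitions from a YAML config
#'
#' The file maps substrate names to key/value geometry blocks using the same
#' keys as [fork_substrate()]. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return Named list of [fork_substrate()] objects.
#' @export
read_substrate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  purrr::imap(cfg, function(x, nm) substrate_from_list(nm, x))
}
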
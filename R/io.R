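# Structured-text readers/writers. All formats are tab-separated with
# '#KEY<TAB>value' header lines; numbers are written with %.17g so a
# write/read round trip is bit-exact. DICOM dialects are recognized but
# not implemented (no DICOM reader is bundled); convert exports to these
# text formats.

fmt_num <- function(x) sprintf("%.17g", x)

read_header <- function(lines, magic, path) {
  if (length(lines) == 0L || !startsWith(lines[1L], paste0("#", magic)))
    stop("'", path, "' is not a ", magic, " file (missing #", magic,
         " header)")
  hdr <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1L]]
    hdr[[kv[1L]]] <- if (length(kv) > 1L) kv[-1L] else ""
    i <- i + 1L
  }
  list(header = hdr, body_start = i)
}

need_attrs <- function(hdr, keys, path) {
  missing <- setdiff(keys, names(hdr))
  if (length(missing))
    stop("'", path, "' is missing required attribute(s): ",
         paste(missing, collapse = ", "))
}

dialect_check <- function(dialect, text_name, dicom_name) {
  if (dialect == dicom_name)
    stop("DICOM input is not supported (no DICOM reader is bundled); ",
         "export the plan data and use the '", text_name, "' dialect")
}

#' Read a source model file
#'
#' @param path path to a `#HDRSOURCE` file: header attributes `name`,
#'   `active_length_cm`, `dose_rate_constant`, a `[radial]` block
#'   (columns r_cm, g) and an `[anisotropy]` block (first column r_cm,
#'   remaining columns the theta grid in degrees).
#' @return a `source_model`.
#' @export
read_source_model <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines, "HDRSOURCE", path)
  need_attrs(h$header, c("name", "active_length_cm", "dose_rate_constant"),
             path)
  rad_at <- which(lines == "[radial]")
  ani_at <- which(lines == "[anisotropy]")
  if (length(rad_at) != 1L || length(ani_at) != 1L)
    stop("'", path, "' must contain one [radial] and one [anisotropy] block")
  rad <- utils::read.table(text = lines[(rad_at + 1L):(ani_at - 1L)],
                           header = TRUE, sep = "\t")
  ani_lines <- lines[(ani_at + 1L):length(lines)]
  ani_lines <- ani_lines[nzchar(ani_lines)]
  theta <- as.numeric(strsplit(ani_lines[1L], "\t")[[1L]][-1L])
  body <- do.call(rbind, lapply(ani_lines[-1L], function(l)
    as.numeric(strsplit(l, "\t")[[1L]])))
  source_model(name = h$header$name,
               active_length_cm = as.numeric(h$header$active_length_cm),
               dose_rate_constant = as.numeric(h$header$dose_rate_constant),
               radial_table = data.frame(r_cm = rad$r_cm, g = rad$g),
               anisotropy_table = list(r_cm = body[, 1L], theta_deg = theta,
                                       F = body[, -1L, drop = FALSE]))
}

#' Write a source model file
#' @param source a `source_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_source_model <- function(source, path) {
  stopifnot(inherits(source, "source_model"))
  at <- source$anisotropy_table
  lines <- c("#HDRSOURCE 1",
             paste0("#name\t", source$name),
             paste0("#active_length_cm\t", fmt_num(source$active_length_cm)),
             paste0("#dose_rate_constant\t",
                    fmt_num(source$dose_rate_constant)),
             "[radial]",
             "r_cm\tg",
             paste(fmt_num(source$radial_table$r_cm),
                   fmt_num(source$radial_table$g), sep = "\t"),
             "[anisotropy]",
             paste(c("r_cm", fmt_num(at$theta_deg)), collapse = "\t"),
             vapply(seq_along(at$r_cm), function(i)
               paste(c(fmt_num(at$r_cm[i]), fmt_num(at$F[i, ])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a treatment plan
#'
#' @param path path to a `#HDRPLAN` file.
#' @param dialect "fixture-text" (implemented) or "dicom-rtplan"
#'   (recognized, not supported).
#' @return a `brachy_plan`.
#' @export
read_plan <- function(path, dialect = c("fixture-text", "dicom-rtplan")) {
  dialect <- match.arg(dialect)
  dialect_check(dialect, "fixture-text", "dicom-rtplan")
  lines <- readLines(path)
  h <- read_header(lines, "HDRPLAN", path)
  need_attrs(h$header, c("source_model", "air_kerma_strength_U"), path)
  body <- lines[h$body_start:length(lines)]
  body <- body[nzchar(body)]
  dw <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("'", path, "' dwell table parse error: ",
                             conditionMessage(e)))
  need <- c("channel", "applicator", "x_mm", "y_mm", "z_mm", "time_s")
  if (!all(need %in% names(dw)))
    stop("'", path, "' dwell table is missing column(s): ",
         paste(setdiff(need, names(dw)), collapse = ", "))
  if (any(is.na(dw$time_s)))
    stop("'", path, "': missing dwell time in record(s) ",
         paste(which(is.na(dw$time_s)), collapse = ", "))
  brachy_plan(
    data.frame(channel = dw$channel, applicator = dw$applicator,
               x = as.numeric(dw$x_mm), y = as.numeric(dw$y_mm),
               z = as.numeric(dw$z_mm), time_s = as.numeric(dw$time_s),
               stringsAsFactors = FALSE),
    air_kerma_strength = as.numeric(h$header$air_kerma_strength_U),
    source_model_id = h$header$source_model,
    fractions = as.integer(h$header$fractions %||% 1L),
    dose_per_fraction_gy = as.numeric(h$header$dose_per_fraction_gy
                                      %||% NA_real_),
    frame_of_reference = h$header$frame_of_reference %||% "default")
}

#' Write a treatment plan
#' @param plan a `brachy_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "brachy_plan"))
  dw <- plan$dwells
  lines <- c("#HDRPLAN 1",
             paste0("#frame_of_reference\t", plan$frame_of_reference),
             paste0("#source_model\t", plan$source_model_id),
             paste0("#air_kerma_strength_U\t",
                    fmt_num(plan$air_kerma_strength)),
             paste0("#fractions\t", plan$fractions),
             paste0("#dose_per_fraction_gy\t",
                    fmt_num(plan$dose_per_fraction_gy)),
             "channel\tapplicator\tx_mm\ty_mm\tz_mm\ttime_s",
             paste(dw$channel, dw$applicator, fmt_num(dw$x), fmt_num(dw$y),
                   fmt_num(dw$z), fmt_num(dw$time_s), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure set
#'
#' @param path path to a `#HDRSTRUCT` file with columns roi, role, poly,
#'   z_mm, x_mm, y_mm (one row per vertex).
#' @param dialect "fixture-text" (implemented) or "dicom-rtstruct"
#'   (recognized, not supported).
#' @param validate check polygons are simple.
#' @return a `structure_set`.
#' @export
read_structures <- function(path,
                            dialect = c("fixture-text", "dicom-rtstruct"),
                            validate = TRUE) {
  dialect <- match.arg(dialect)
  dialect_check(dialect, "fixture-text", "dicom-rtstruct")
  lines <- readLines(path)
  h <- read_header(lines, "HDRSTRUCT", path)
  body <- lines[h$body_start:length(lines)]
  tab <- utils::read.table(text = body[nzchar(body)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  need <- c("roi", "role", "poly", "z_mm", "x_mm", "y_mm")
  if (!all(need %in% names(tab)))
    stop("'", path, "' is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  rois <- list()
  for (nm in unique(tab$roi)) {
    sub <- tab[tab$roi == nm, ]
    polys <- lapply(unique(sub$poly), function(p) {
      v <- sub[sub$poly == p, ]
      list(z = as.numeric(v$z_mm[1L]),
           xy = cbind(as.numeric(v$x_mm), as.numeric(v$y_mm)))
    })
    rois[[length(rois) + 1L]] <-
      list(name = nm, role = sub$role[1L], polygons = polys)
  }
  structure_set(rois,
                slice_spacing_mm =
                  as.numeric(h$header$slice_spacing_mm %||% 2.5),
                frame_of_reference = h$header$frame_of_reference %||%
                  "default",
                validate = validate)
}

#' Write a structure set
#' @param structures a `structure_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  stopifnot(inherits(structures, "structure_set"))
  rows <- character(0)
  for (roi in structures$rois) {
    pid <- 0L
    for (pg in roi$polygons) {
      pid <- pid + 1L
      rows <- c(rows, paste(roi$name, roi$role, pid, fmt_num(pg$z),
                            fmt_num(pg$xy[, 1L]), fmt_num(pg$xy[, 2L]),
                            sep = "\t"))
    }
  }
  writeLines(c("#HDRSTRUCT 1",
               paste0("#frame_of_reference\t",
                      structures$frame_of_reference),
               paste0("#slice_spacing_mm\t",
                      fmt_num(structures$slice_spacing_mm)),
               "roi\trole\tpoly\tz_mm\tx_mm\ty_mm", rows), path)
  invisible(path)
}

#' Read a dose volume array container
#' @param path path to a `#HDRDOSE` file.
#' @return a `dose_volume`.
#' @export
read_dose_volume <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines, "HDRDOSE", path)
  need_attrs(h$header, c("origin_mm", "spacing_mm", "dims"), path)
  g <- grid_spec(as.numeric(h$header$origin_mm),
                 as.numeric(h$header$spacing_mm),
                 as.integer(h$header$dims))
  vals <- scan(text = lines[h$body_start:length(lines)], quiet = TRUE)
  if (length(vals) != prod(g$dims))
    stop("'", path, "' has ", length(vals), " values but dims imply ",
         prod(g$dims))
  dose_volume(array(vals, g$dims), g,
              metadata = list(units = (h$header$units %||% "cGy")[1L]))
}

#' Write a dose volume array container
#' @param dose a `dose_volume`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_volume <- function(dose, path) {
  stopifnot(inherits(dose, "dose_volume"))
  g <- dose$grid
  vals <- as.vector(dose$values)
  rows <- vapply(seq_len(g$dims[2L] * g$dims[3L]), function(r)
    paste(fmt_num(vals[((r - 1L) * g$dims[1L] + 1L):(r * g$dims[1L])]),
          collapse = " "), "")
  writeLines(c("#HDRDOSE 1",
               paste0("#origin_mm\t", paste(fmt_num(g$origin),
                                            collapse = "\t")),
               paste0("#spacing_mm\t", paste(fmt_num(g$spacing),
                                             collapse = "\t")),
               paste0("#dims\t", paste(g$dims, collapse = "\t")),
               paste0("#units\t", dose$metadata$units %||% "cGy"),
               rows), path)
  invisible(path)
}

#' Read reference points
#' @param path path to a `#HDRPOINTS` file with columns name, x_mm, y_mm,
#'   z_mm and optionally tps_dose_cgy.
#' @return data.frame.
#' @export
read_reference_points <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines, "HDRPOINTS", path)
  body <- lines[h$body_start:length(lines)]
  tab <- utils::read.table(text = body[nzchar(body)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(tab)))
    stop("'", path, "' is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  for (cc in setdiff(names(tab), "name")) tab[[cc]] <- as.numeric(tab[[cc]])
  tab
}

#' Write reference points
#' @param points data.frame with name, x_mm, y_mm, z_mm and optional
#'   tps_dose_cgy.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_points <- function(points, path) {
  cols <- intersect(c("name", "x_mm", "y_mm", "z_mm", "tps_dose_cgy"),
                    names(points))
  rows <- do.call(paste, c(lapply(cols, function(cc) {
    v <- points[[cc]]
    if (is.numeric(v)) fmt_num(v) else v
  }), sep = "\t"))
  writeLines(c("#HDRPOINTS 1", paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Export a DVH curve as delimited text
#' @param dvh a `dvh` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# structure\t", dvh$structure),
               paste0("# volume_cc\t", fmt_num(dvh$volume_cc)),
               paste0("# applicator_excluded\t", dvh$applicator_excluded)),
             con)
  utils::write.table(dvh$curve, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
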
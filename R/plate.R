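#' Multiwell plate geometry
#'
#' Defines a plate by its row/column counts, per-well capacity and depth.
#' Named formats cover the plate types the delivery robot supports, from
#' 6-well to 384-well, with well depths of 5--30 mm (300 uL to 2 mL for a
#' 96-well plate).
#'
#' @param format Either a named format string (one of
#'   `names(plate_formats())`) or `NULL` to give the geometry explicitly.
#' @param rows,cols Row and column counts (rows are lettered A, B, ...).
#' @param well_capacity_ul Well capacity in microlitres.
#' @param well_depth_mm Well depth in millimetres (5--30 supported).
#' @param format_name Label kept with the spec.
#' @return An object of class `plate_spec`.
#' @examples
#' plate_spec("96-medium")
#' plate_spec(NULL, rows = 2, cols = 3, well_capacity_ul = 1000, well_depth_mm = 10)
#' @export
plate_spec <- function(format = "96-medium", rows = NULL, cols = NULL,
                       well_capacity_ul = NULL, well_depth_mm = NULL,
                       format_name = NULL) {
  if (!is.null(format)) {
    fmts <- plate_formats()
    if (!format %in% names(fmts)) {
      stop("unknown plate format '", format, "'; known: ",
           paste(names(fmts), collapse = ", "), call. = FALSE)
    }
    f <- fmts[[format]]
    rows <- f$rows; cols <- f$cols
    well_capacity_ul <- f$well_capacity_ul
    well_depth_mm <- f$well_depth_mm
    format_name <- format
  }
  stopifnot(is.numeric(rows), is.numeric(cols), rows >= 1, cols >= 1,
            rows == round(rows), cols == round(cols))
  if (rows > 16L) stop("at most 16 rows (letters A-P) are supported", call. = FALSE)
  if (is.null(well_capacity_ul) || well_capacity_ul <= 0)
    stop("well_capacity_ul must be > 0", call. = FALSE)
  if (is.null(well_depth_mm)) well_depth_mm <- 10
  if (well_depth_mm < 5 || well_depth_mm > 30)
    stop("well_depth_mm must be within 5-30 mm", call. = FALSE)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         well_capacity_ul = well_capacity_ul,
         well_depth_mm = well_depth_mm,
         format_name = if (is.null(format_name)) "custom" else format_name),
    class = "plate_spec"
  )
}

#' Named plate formats
#'
#' Capacities follow the supported plate range: medium-depth 96-well plates
#' hold 600 uL, deep 96-well plates 2 mL, 384-well plates 225 uL, and the
#' lower-density formats progressively larger volumes (48-well 5 mL, 24-well
#' 10 mL, 6-well 16.8 mL).
#'
#' @return Named list of geometry parameter lists.
#' @export
plate_formats <- function() {
  list(
    "6"         = list(rows = 2L,  cols = 3L,  well_capacity_ul = 16800, well_depth_mm = 18),
    "24"        = list(rows = 4L,  cols = 6L,  well_capacity_ul = 10000, well_depth_mm = 18),
    "48"        = list(rows = 6L,  cols = 8L,  well_capacity_ul = 5000,  well_depth_mm = 18),
    "96-medium" = list(rows = 8L,  cols = 12L, well_capacity_ul = 600,   well_depth_mm = 11),
    "96-deep"   = list(rows = 8L,  cols = 12L, well_capacity_ul = 2000,  well_depth_mm = 30),
    "384"       = list(rows = 16L, cols = 24L, well_capacity_ul = 225,   well_depth_mm = 11)
  )
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> %s: %d x %d wells, %g uL capacity, %g mm deep\n",
              x$format_name, x$rows, x$cols, x$well_capacity_ul, x$well_depth_mm))
  invisible(x)
}

#' Canonical well names
#'
#' Wells are named by an uppercase row letter followed by a 1-based column
#' number ("A1"), matching the robot's command grammar.
#'
#' @param row Integer row index (1 = "A") or row letter.
#' @param col Integer 1-based column.
#' @return Character well id(s).
#' @export
well_id <- function(row, col) {
  if (is.character(row)) row <- match(toupper(row), LETTERS)
  stopifnot(all(row >= 1), all(row <= 16), all(col >= 1))
  paste0(LETTERS[row], as.integer(col))
}

#' Parse a well name into row/column indices
#'
#' @param well Character well id like "B7" (case-insensitive).
#' @param plate Optional `plate_spec` for bounds checking.
#' @return data.frame with columns `well`, `row`, `col` (canonical well id).
#' @export
parse_well <- function(well, plate = NULL) {
  m <- regmatches(well, regexec("^([A-Pa-p])([0-9]+)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well id(s): ", paste(well[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, function(g) match(toupper(g[2]), LETTERS), 1L)
  col <- vapply(m, function(g) as.integer(g[3]), 1L)
  if (any(col < 1L)) stop("column numbers are 1-based", call. = FALSE)
  if (!is.null(plate)) {
    out_of_bounds <- row > plate$rows | col > plate$cols
    if (any(out_of_bounds)) {
      stop("well(s) outside the ", plate$rows, "x", plate$cols, " plate: ",
           paste(well[out_of_bounds], collapse = ", "), call. = FALSE)
    }
  }
  data.frame(well = well_id(row, col), row = row, col = col,
             stringsAsFactors = FALSE)
}

#' All wells of a plate in row-major order
#' @param plate A `plate_spec`.
#' @return Character vector of well ids.
#' @export
plate_wells <- function(plate) {
  as.vector(t(outer(seq_len(plate$rows), seq_len(plate$cols), well_id)))
}

#' Plate traversal orders
#'
#' `snake` reverses the column direction on each successive row (minimising
#' plate travel); `typewriter` restarts every row at column 1. The snake
#' starts left-to-right on row A by default; `first_direction = "rtl"`
#' flips the starting direction.
#'
#' @param plate A `plate_spec`.
#' @param pattern `"snake"` or `"typewriter"`.
#' @param first_direction `"ltr"` (default) or `"rtl"`, the direction of row A.
#' @return Character vector of well ids visiting every well exactly once.
#' @examples
#' traversal_order(plate_spec("96-medium"))[1:14]
#' @export
traversal_order <- function(plate, pattern = c("snake", "typewriter"),
                            first_direction = c("ltr", "rtl")) {
  pattern <- match.arg(pattern)
  first_direction <- match.arg(first_direction)
  cols_fwd <- seq_len(plate$cols)
  rows <- seq_len(plate$rows)
  out <- lapply(rows, function(r) {
    cols <- cols_fwd
    if (pattern == "snake") {
      reverse_row <- (r %% 2L == 0L) == (first_direction == "ltr")
      if (reverse_row) cols <- rev(cols)
    } else if (first_direction == "rtl") {
      cols <- rev(cols)
    }
    well_id(r, cols)
  })
  unlist(out)
}

#' @rdname traversal_order
#' @export
snake_order <- function(plate, first_direction = c("ltr", "rtl")) {
  traversal_order(plate, "snake", match.arg(first_direction))
}

new_plate_map <- function(plate, df) {
  stopifnot(all(c("well", "fluid", "concentration", "volume_ul") %in% names(df)))
  pw <- parse_well(df$well, plate)
  df$well <- pw$well
  if (any(df$volume_ul > plate$well_capacity_ul, na.rm = TRUE)) {
    stop("loaded volume exceeds well capacity (",
         plate$well_capacity_ul, " uL)", call. = FALSE)
  }
  structure(list(plate = plate, assignments = df), class = "plate_map")
}

#' @export
print.plate_map <- function(x, ...) {
  cat(sprintf("<plate_map> %s plate, %d wells assigned, fluids: %s\n",
              x$plate$format_name, nrow(x$assignments),
              paste(unique(x$assignments$fluid), collapse = ", ")))
  invisible(x)
}

#' Assign two fluids to alternating wells along a traversal order
#'
#' The first well of `order` receives `fluid_a`, the second `fluid_b`, and
#' so on. Used, e.g., to lay out a full 96-well plate of alternating buffer
#' and fluorescein wells for the carryover assay.
#'
#' @param plate A `plate_spec`.
#' @param fluid_a,fluid_b Fluid names; `fluid_a` is delivered first.
#' @param order Well order (defaults to the snake traversal).
#' @param volume_ul Loaded volume per well (defaults to plate capacity).
#' @param concentration_a,concentration_b Optional concentrations recorded
#'   with each fluid.
#' @return A `plate_map`.
#' @export
alternating_map <- function(plate, fluid_a, fluid_b,
                            order = snake_order(plate),
                            volume_ul = plate$well_capacity_ul,
                            concentration_a = NA_real_,
                            concentration_b = NA_real_) {
  if (length(order) == 0L) stop("empty well order", call. = FALSE)
  if (!setequal(order, plate_wells(plate)) || anyDuplicated(order)) {
    stop("order must cover every plate well exactly once", call. = FALSE)
  }
  idx <- seq_along(order)
  df <- data.frame(
    well = order,
    fluid = ifelse(idx %% 2L == 1L, fluid_a, fluid_b),
    concentration = ifelse(idx %% 2L == 1L, concentration_a, concentration_b),
    volume_ul = volume_ul,
    stringsAsFactors = FALSE
  )
  m <- new_plate_map(plate, df)
  m$order <- order
  m
}

#' Canonical carryover assay plate
#'
#' A full plate of alternating fluorescein-dye and water wells visited in a
#' snake pattern, with the dye first so that every water well immediately
#' follows a dye well: a 96-well plate yields exactly 48 dye-to-water
#' switches.
#'
#' @param plate A `plate_spec` (default medium-depth 96-well, 600 uL/well).
#' @param dye,buffer Fluid names.
#' @param dye_concentration Dye concentration recorded with the map
#'   (default 5 ug/mL fluorescein).
#' @return A `plate_map` with an `order` element (the scan order).
#' @export
carryover_assay_map <- function(plate = plate_spec("96-medium"),
                                dye = "fluorescein", buffer = "water",
                                dye_concentration = 5) {
  alternating_map(plate, dye, buffer, concentration_a = dye_concentration)
}

#' Count transitions between two fluids along a scan order
#'
#' @param map A `plate_map`.
#' @param from,to Fluid names.
#' @param order Well order (defaults to the map's own order).
#' @return Integer count of consecutive `from` -> `to` pairs.
#' @export
count_fluid_switches <- function(map, from, to, order = map$order) {
  if (is.null(order)) stop("no well order available", call. = FALSE)
  fl <- map$assignments$fluid[match(order, map$assignments$well)]
  sum(fl[-length(fl)] == from & fl[-1] == to, na.rm = TRUE)
}

#' Solvent screen plate layout
#'
#' Each solvent is tested at each concentration, every test well preceded by
#' a buffer-control well, and the sequence ends on a control: the delivered
#' sequence is control, s1@c1, control, s1@c2, control, ..., control, for a
#' total of 2 * n_solvents * n_concentrations + 1 wells. Fourteen solvents
#' at 1% and 5% give the 57-well screen.
#'
#' @param solvents Character vector of solvent names.
#' @param concentrations Numeric concentrations (percent v/v), default `c(1, 5)`.
#' @param control Control fluid name.
#' @param plate A `plate_spec`; the sequence must fit on it.
#' @param volume_ul Loaded volume per well (default 700 uL).
#' @return A `plate_map` whose `order` element is the delivery sequence.
#' @examples
#' m <- screen_map(default_solvents())
#' length(m$order)  # 57
#' @export
screen_map <- function(solvents, concentrations = c(1, 5),
                       control = "buffer",
                       plate = plate_spec("96-medium"),
                       volume_ul = 700) {
  if (length(solvents) < 1L) stop("need at least one solvent", call. = FALSE)
  if (length(concentrations) < 1L) stop("need at least one concentration", call. = FALSE)
  fluid <- character(0); conc <- numeric(0)
  for (s in solvents) {
    for (cc in concentrations) {
      fluid <- c(fluid, control, s)
      conc <- c(conc, NA_real_, cc)
    }
  }
  fluid <- c(fluid, control)
  conc <- c(conc, NA_real_)
  n <- length(fluid)
  stopifnot(n == 2L * length(solvents) * length(concentrations) + 1L)
  wells <- snake_order(plate)
  if (n > length(wells)) {
    stop("screen sequence (", n, " wells) does not fit on the ",
         plate$rows * plate$cols, "-well plate", call. = FALSE)
  }
  volume_ul <- min(volume_ul, plate$well_capacity_ul)
  df <- data.frame(well = wells[seq_len(n)], fluid = fluid,
                   concentration = conc, volume_ul = volume_ul,
                   stringsAsFactors = FALSE)
  m <- new_plate_map(plate, df)
  m$order <- df$well
  m
}

#' Default solvent panel for the suppression screen
#'
#' Fourteen common solvents and carriers. Only part of the panel is named in
#' the assay this emulates; the remainder are representative choices.
#'
#' @return Character vector of 14 solvent names.
#' @export
default_solvents <- function() {
  c("DMSO", "ethanol", "methanol", "isopropanol", "acetonitrile",
    "acetone", "dimethylformamide", "glycerol", "ethylene-glycol",
    "propylene-glycol", "PEG-400", "Tween-20", "Triton-X-100", "butanol")
}

#' Geometric dilution series
#'
#' @param top Highest concentration (must be > 0).
#' @param factor Fold dilution per step (> 1).
#' @param n Number of concentrations.
#' @return Numeric vector of length `n`, strictly decreasing:
#'   `top, top/factor, ..., top/factor^(n-1)`.
#' @examples
#' dilution_series(11.5e-3, 10, 7)  # 11.5 mM down to 11.5 nM
#' @export
dilution_series <- function(top, factor, n) {
  if (!is.numeric(top) || top <= 0) stop("top must be > 0", call. = FALSE)
  if (!is.numeric(factor) || factor <= 1) stop("factor must be > 1", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  top / factor^(seq_len(n) - 1)
}

#' Read / write plate maps as CSV
#'
#' The file format is a header-mandatory CSV with columns
#' `well,fluid,concentration,volume_ul`.
#'
#' @param map A `plate_map`.
#' @param path File path.
#' @param plate `plate_spec` used to validate wells on read.
#' @return `read_plate_map` returns a `plate_map`; `write_plate_map` its path,
#'   invisibly.
#' @export
write_plate_map <- function(map, path) {
  utils::write.csv(map$assignments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path, plate = plate_spec("96-medium")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "fluid", "concentration", "volume_ul")
  if (!all(need %in% names(df))) {
    stop("plate map CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  m <- new_plate_map(plate, df[, need])
  m$order <- df$well
  m
}
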
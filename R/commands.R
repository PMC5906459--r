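#' Serial command tokens for plate and tube positioning
#'
#' The robot is driven by a tiny serial grammar: `"0"` homes (servo raised,
#' plate at A1); `[wellRow][wellColumn][+ or -]` raises the servo arm, moves
#' the plate to the named well, then either keeps the tube raised (`+`) or
#' lowers it into the well (`-`). Commands are strung together with `;` for
#' immediate sequential execution, e.g. `"A1-;A2-"`.
#'
#' `command_tokens()` builds a token table; `cmd_home()` and `cmd_move()` are
#' single-token conveniences.
#'
#' @param kind Character vector, `"home"` or `"move"`.
#' @param well Well ids (`NA` for home tokens).
#' @param end_state `"raised"` or `"lowered"` for moves, `NA` for home.
#' @return data.frame of class `command_tokens` with columns
#'   `kind`, `well`, `end_state`.
#' @export
command_tokens <- function(kind, well = NA_character_, end_state = NA_character_) {
  df <- data.frame(kind = kind, well = well, end_state = end_state,
                   stringsAsFactors = FALSE)
  validate_tokens(df)
  class(df) <- c("command_tokens", "data.frame")
  df
}

#' @rdname command_tokens
#' @export
cmd_home <- function() command_tokens("home")

#' @rdname command_tokens
#' @param lower Logical; lower the tube at the destination (`-`) or keep it
#'   raised (`+`).
#' @export
cmd_move <- function(well, lower = TRUE) {
  command_tokens("move", well = toupper(well),
                 end_state = ifelse(lower, "lowered", "raised"))
}

validate_tokens <- function(df) {
  stopifnot(all(df$kind %in% c("home", "move")))
  is_move <- df$kind == "move"
  if (any(is_move & (is.na(df$well) | is.na(df$end_state))))
    stop("move tokens need a well and an end_state", call. = FALSE)
  if (any(!is_move & (!is.na(df$well) | !is.na(df$end_state))))
    stop("home tokens carry no well or end_state", call. = FALSE)
  if (any(is_move & !df$end_state %in% c("raised", "lowered")))
    stop("end_state must be 'raised' or 'lowered'", call. = FALSE)
  if (any(is_move)) parse_well(df$well[is_move])
  invisible(df)
}

#' Encode command tokens to a serial command string
#'
#' @param tokens A `command_tokens` table (or data.frame with the same
#'   columns).
#' @return Single command string, segments joined by `;`. Home encodes as
#'   `"0"`; moves as the well id followed by `+` (stay raised) or `-`
#'   (lower).
#' @examples
#' encode_commands(rbind(cmd_move("A1"), cmd_move("A2")))  # "A1-;A2-"
#' @export
encode_commands <- function(tokens) {
  validate_tokens(tokens)
  seg <- ifelse(tokens$kind == "home", "0",
                paste0(toupper(tokens$well),
                       ifelse(tokens$end_state == "lowered", "-", "+")))
  paste(seg, collapse = ";")
}

#' Parse a serial command string into tokens
#'
#' Parsing is case-insensitive on the row letter; row letters run A-P and
#' columns may have multiple digits (up to 24 for a 384-well plate).
#' `parse_commands(encode_commands(x))` is the identity on valid token
#' tables.
#'
#' @param s Command string, segments separated by `;`.
#' @return A `command_tokens` table.
#' @examples
#' parse_commands("A1-;A2-")
#' parse_commands("0")
#' @export
parse_commands <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  segs <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (length(segs) == 0L) stop("empty command string", call. = FALSE)
  toks <- lapply(segs, function(seg) {
    if (!nzchar(seg)) stop("empty command segment in '", s, "'", call. = FALSE)
    if (seg == "0") return(cmd_home())
    m <- regexec("^([A-Pa-p])([0-9]+)([+-])$", seg)[[1]]
    g <- regmatches(seg, list(m))[[1]]
    if (length(g) != 4L) {
      stop("malformed command segment '", seg, "'", call. = FALSE)
    }
    col <- as.integer(g[3])
    if (col < 1L || col > 24L) {
      stop("column out of range in segment '", seg, "'", call. = FALSE)
    }
    cmd_move(paste0(toupper(g[2]), col), lower = g[4] == "-")
  })
  out <- do.call(rbind, toks)
  class(out) <- c("command_tokens", "data.frame")
  rownames(out) <- NULL
  out
}

#' Render a well visit sequence as command strings
#'
#' Each visited well becomes a lowered move; an optional final home token
#' returns the system to its idle state.
#'
#' @param order Character vector of well ids in visit order.
#' @param home_at_end Append a home command?
#' @return Command string.
#' @export
commands_for_order <- function(order, home_at_end = FALSE) {
  toks <- do.call(rbind, lapply(order, cmd_move))
  if (home_at_end) toks <- rbind(toks, cmd_home())
  class(toks) <- c("command_tokens", "data.frame")
  encode_commands(toks)
}
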
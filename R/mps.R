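# MPS reading and writing. Both fixed- and free-format files are handled by
# whitespace tokenization (fixed-format column positions are a superset of
# this interpretation for the files this package targets). Supported
# sections: NAME, OBJSENSE, ROWS, COLUMNS (with INTORG/INTEND markers), RHS,
# RANGES, BOUNDS, ENDATA.

#' Read an MPS file
#'
#' @param path Path to a fixed- or free-format MPS file.
#' @param sense Objective sense used when the file has no `OBJSENSE` section
#'   (the historical default is minimization).
#' @param integer_bounds Default bounds for variables declared integer via
#'   `MARKER` with no `BOUNDS` entry: `"nonneg"` for `[0, Inf)` or
#'   `"binary"` for `[0, 1]` (both conventions occur in the wild; the
#'   default keeps `[0, Inf)`).
#' @return A [mip_instance()]. An RHS entry on the objective row `r` is kept
#'   as the objective constant `-r`. `RANGES` entries are expanded into a
#'   second single-sense constraint row.
#' @export
read_mps <- function(path, sense = c("minimize", "maximize"),
                     integer_bounds = c("nonneg", "binary")) {
  sense <- match.arg(sense)
  integer_bounds <- match.arg(integer_bounds)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)

  fmt_error <- function(lineno, msg) {
    stop_morseopt(sprintf("MPS format error at line %d: %s", lineno, msg),
                  "morseopt_format_error")
  }

  name <- "unnamed"
  obj_row <- NULL
  row_sense <- character(0)  # named by row
  col_order <- character(0)
  col_int <- logical(0)      # named by column: declared inside INTORG/INTEND
  entries <- list()          # list of c(col, row, val)
  objective <- list()
  rhs_map <- list()
  ranges_map <- list()
  bounds <- list()           # var -> list(lb=, ub=, vtype=)
  section <- NULL
  in_integer <- FALSE
  saw_endata <- FALSE
  objsense_pending <- FALSE

  for (lineno in seq_along(raw)) {
    line <- raw[lineno]
    if (!nzchar(line) || startsWith(line, "*")) next
    is_header <- !grepl("^[ \t]", line)
    toks <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (is_header) {
      head <- toupper(toks[1])
      if (objsense_pending && head %in% c("MAX", "MIN", "MAXIMIZE", "MINIMIZE")) {
        sense <- if (startsWith(head, "MAX")) "maximize" else "minimize"
        objsense_pending <- FALSE
        next
      }
      objsense_pending <- FALSE
      if (head == "NAME") {
        if (length(toks) >= 2) name <- toks[2]
        section <- "NAME"
      } else if (head == "OBJSENSE") {
        section <- "OBJSENSE"
        if (length(toks) >= 2) {
          sense <- if (startsWith(toupper(toks[2]), "MAX")) "maximize" else "minimize"
        } else {
          objsense_pending <- TRUE
        }
      } else if (head %in% c("ROWS", "COLUMNS", "RHS", "RANGES", "BOUNDS")) {
        section <- head
      } else if (head == "ENDATA") {
        saw_endata <- TRUE
        break
      } else {
        fmt_error(lineno, paste0("unknown section '", toks[1], "'"))
      }
      next
    }
    if (is.null(section)) fmt_error(lineno, "data before any section header")
    if (section == "OBJSENSE") {
      sense <- if (startsWith(toupper(toks[1]), "MAX")) "maximize" else "minimize"
      objsense_pending <- FALSE
      next
    }
    if (section == "ROWS") {
      if (length(toks) < 2) fmt_error(lineno, "ROWS entry needs type and name")
      type <- toupper(toks[1])
      rname <- toks[2]
      if (type == "N") {
        if (is.null(obj_row)) obj_row <- rname  # later free rows ignored
      } else if (type %in% c("L", "G", "E")) {
        row_sense[rname] <- c(L = "<=", G = ">=", E = "=")[[type]]
      } else {
        fmt_error(lineno, paste0("unknown row type '", toks[1], "'"))
      }
    } else if (section == "COLUMNS") {
      if (length(toks) >= 3 && toupper(toks[2]) == "'MARKER'") {
        marker <- toupper(toks[length(toks)])
        if (marker == "'INTORG'") in_integer <- TRUE
        else if (marker == "'INTEND'") in_integer <- FALSE
        else fmt_error(lineno, "unrecognized MARKER")
        next
      }
      if (length(toks) < 3 || length(toks) %% 2 == 0) {
        fmt_error(lineno, "COLUMNS entry needs column, then row/value pairs")
      }
      col <- toks[1]
      if (!(col %in% col_order)) {
        col_order <- c(col_order, col)
        col_int[col] <- in_integer
      }
      for (k in seq(2, length(toks) - 1, by = 2)) {
        rname <- toks[k]
        val <- suppressWarnings(as.numeric(toks[k + 1]))
        if (is.na(val)) fmt_error(lineno, paste0("bad numeric '", toks[k + 1], "'"))
        if (!is.null(obj_row) && rname == obj_row) {
          objective[[col]] <- (objective[[col]] %||% 0) + val
        } else if (rname %in% names(row_sense)) {
          entries[[length(entries) + 1]] <- list(col = col, row = rname, val = val)
        } else {
          fmt_error(lineno, paste0("unknown row '", rname, "'"))
        }
      }
    } else if (section %in% c("RHS", "RANGES")) {
      # first token is the rhs/range set name; tolerate files that omit it
      off <- if (length(toks) %% 2 == 1) 1 else 0
      if (length(toks) < off + 2) fmt_error(lineno, "entry needs row/value pairs")
      for (k in seq(off + 1, length(toks) - 1, by = 2)) {
        rname <- toks[k]
        val <- suppressWarnings(as.numeric(toks[k + 1]))
        if (is.na(val)) fmt_error(lineno, paste0("bad numeric '", toks[k + 1], "'"))
        if (section == "RHS") rhs_map[[rname]] <- val else ranges_map[[rname]] <- val
      }
    } else if (section == "BOUNDS") {
      type <- toupper(toks[1])
      if (type %in% c("FR", "MI", "PL", "BV")) {
        if (length(toks) < 3) fmt_error(lineno, "BOUNDS entry needs type, set, column")
        var <- toks[3]; val <- NA_real_
      } else {
        if (length(toks) < 4) fmt_error(lineno, "BOUNDS entry needs type, set, column, value")
        var <- toks[3]
        val <- suppressWarnings(as.numeric(toks[4]))
        if (is.na(val)) fmt_error(lineno, paste0("bad numeric '", toks[4], "'"))
      }
      b <- bounds[[var]] %||% list(lb = NA_real_, ub = NA_real_, vtype = NA_character_)
      if (type == "UP") b$ub <- val
      else if (type == "LO") b$lb <- val
      else if (type == "FX") { b$lb <- val; b$ub <- val }
      else if (type == "FR") { b$lb <- -Inf; b$ub <- Inf }
      else if (type == "MI") b$lb <- -Inf
      else if (type == "PL") b$ub <- Inf
      else if (type == "BV") { b$lb <- 0; b$ub <- 1; b$vtype <- "Binary" }
      else if (type == "UI") { b$ub <- val; b$vtype <- "Integer" }
      else if (type == "LI") { b$lb <- val; b$vtype <- "Integer" }
      else fmt_error(lineno, paste0("unknown bound type '", toks[1], "'"))
      bounds[[var]] <- b
    } else if (section %in% c("NAME")) {
      fmt_error(lineno, "unexpected data line")
    }
  }
  if (!saw_endata) {
    stop_morseopt("MPS format error: missing ENDATA", "morseopt_format_error")
  }
  if (!length(col_order)) {
    stop_morseopt("MPS format error: no columns", "morseopt_format_error")
  }

  # assemble variables
  vtype <- ifelse(col_int[col_order], "Integer", "Continuous")
  lb <- numeric(length(col_order)); ub <- numeric(length(col_order))
  for (i in seq_along(col_order)) {
    v <- col_order[i]
    b <- bounds[[v]]
    has_bnd <- !is.null(b)
    if (vtype[i] == "Integer" && !has_bnd) {
      lb[i] <- 0
      ub[i] <- if (integer_bounds == "binary") 1 else Inf
    } else {
      lb[i] <- if (has_bnd && !is.na(b$lb)) b$lb else 0
      ub[i] <- if (has_bnd && !is.na(b$ub)) b$ub else Inf
      # UP with a negative value and no explicit lower bound: keep lb = 0
      # only if consistent, else drop to -Inf (the common dialect)
      if (has_bnd && !is.na(b$ub) && is.na(b$lb) && b$ub < 0) lb[i] <- -Inf
    }
    if (has_bnd && !is.na(b$vtype)) vtype[i] <- b$vtype
  }
  variables <- data.frame(name = col_order, vtype = vtype, lb = lb, ub = ub,
                          stringsAsFactors = FALSE)

  # assemble constraints (RANGES expand to a second row)
  rnames <- names(row_sense)
  A <- matrix(0, length(rnames), length(col_order),
              dimnames = list(rnames, col_order))
  for (e in entries) A[e$row, e$col] <- A[e$row, e$col] + e$val
  rhs <- vapply(rnames, function(r) rhs_map[[r]] %||% 0, numeric(1))
  sen <- unname(row_sense[rnames])
  extra <- list()
  for (r in names(ranges_map)) {
    if (!(r %in% rnames)) next
    rg <- ranges_map[[r]]
    i <- match(r, rnames)
    if (sen[i] == "<=") {
      extra[[length(extra) + 1]] <- list(row = A[i, ], sense = ">=", rhs = rhs[i] - abs(rg))
    } else if (sen[i] == ">=") {
      extra[[length(extra) + 1]] <- list(row = A[i, ], sense = "<=", rhs = rhs[i] + abs(rg))
    } else {
      # E row: becomes [rhs, rhs + rg] for rg >= 0, [rhs + rg, rhs] otherwise
      lo <- rhs[i] + min(rg, 0); hi <- rhs[i] + max(rg, 0)
      sen[i] <- ">="; rhs[i] <- lo
      extra[[length(extra) + 1]] <- list(row = A[i, ], sense = "<=", rhs = hi)
    }
  }
  if (length(extra)) {
    A <- rbind(A, do.call(rbind, lapply(extra, `[[`, "row")))
    sen <- c(sen, vapply(extra, `[[`, character(1), "sense"))
    rhs <- c(rhs, vapply(extra, function(e) e$rhs, numeric(1)))
  }

  obj <- vapply(names(objective), function(v) objective[[v]], numeric(1))
  constant <- -(rhs_map[[obj_row]] %||% 0)

  mip_instance(name, variables, obj, sense,
               constraints = list(A = A, sense = sen, rhs = rhs),
               constant = constant)
}

#' Write an instance to a free-format MPS file
#'
#' Inverse of [read_mps()] up to canonicalization: re-reading the written
#' file yields an instance with the same variables, types, bounds, objective,
#' constraints and sense.
#'
#' @param instance A [mip_instance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mps <- function(instance, path) {
  stopifnot(inherits(instance, "mip_instance"))
  vars <- instance$variables
  cons <- instance$constraints
  m <- length(cons$rhs)
  rname <- sprintf("R%04d", seq_len(m))
  out <- c(
    paste("NAME", instance$name),
    if (instance$sense == "maximize") c("OBJSENSE", "    MAX"),
    "ROWS",
    " N  OBJ",
    if (m) paste0(" ", c("<=" = "L", ">=" = "G", "=" = "E")[cons$sense], "  ", rname)
  )
  cols <- character(0)
  fmt <- function(x) format(x, scientific = FALSE, digits = 15, trim = TRUE)
  intmask <- vars$vtype != "Continuous"
  marker_open <- FALSE
  for (i in seq_len(nrow(vars))) {
    v <- vars$name[i]
    if (intmask[i] && !marker_open) {
      cols <- c(cols, "    MARKER1 'MARKER' 'INTORG'"); marker_open <- TRUE
    }
    if (!intmask[i] && marker_open) {
      cols <- c(cols, "    MARKER2 'MARKER' 'INTEND'"); marker_open <- FALSE
    }
    cv <- instance$objective[v]
    lines_v <- character(0)
    if (length(cv) == 1 && !is.na(cv)) {
      lines_v <- c(lines_v, paste("   ", v, "OBJ", fmt(unname(cv))))
    }
    if (m) {
      nz <- which(cons$A[, match(v, cons$var_names)] != 0)
      for (r in nz) {
        lines_v <- c(lines_v, paste("   ", v, rname[r], fmt(cons$A[r, match(v, cons$var_names)])))
      }
    }
    if (!length(lines_v)) {
      # ensure the column exists even if it appears nowhere
      lines_v <- paste("   ", v, "OBJ", "0")
    }
    cols <- c(cols, lines_v)
  }
  if (marker_open) cols <- c(cols, "    MARKER2 'MARKER' 'INTEND'")
  out <- c(out, "COLUMNS", cols, "RHS")
  if (m) {
    nzr <- which(cons$rhs != 0)
    for (r in nzr) out <- c(out, paste("    RHS1", rname[r], fmt(cons$rhs[r])))
  }
  if (instance$constant != 0) {
    out <- c(out, paste("    RHS1 OBJ", fmt(-instance$constant)))
  }
  bnd <- character(0)
  for (i in seq_len(nrow(vars))) {
    v <- vars$name[i]
    lbv <- vars$lb[i]; ubv <- vars$ub[i]
    if (vars$vtype[i] == "Binary") {
      if (lbv == 0 && ubv == 1) { bnd <- c(bnd, paste(" BV BND1", v)); next }
    }
    if (lbv == ubv) { bnd <- c(bnd, paste(" FX BND1", v, fmt(lbv))); next }
    if (!is.finite(lbv)) bnd <- c(bnd, paste(" MI BND1", v))
    else if (lbv != 0) bnd <- c(bnd, paste(" LO BND1", v, fmt(lbv)))
    if (is.finite(ubv)) bnd <- c(bnd, paste(" UP BND1", v, fmt(ubv)))
    else if (vars$vtype[i] != "Continuous") bnd <- c(bnd, paste(" PL BND1", v))
  }
  if (length(bnd)) out <- c(out, "BOUNDS", bnd)
  out <- c(out, "ENDATA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
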
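#' @importFrom stats approx optimize setNames
#' @importFrom utils read.csv write.csv head tail
NULL

.ROLES <- c("adsorbate", "silanol", "framework", "terminal_H")

#' Create a molecular/slab structure
#'
#' Atoms with Cartesian coordinates, an optional 2D lattice (slab models are
#' periodic in two dimensions), and a per-atom role tag distinguishing the
#' adsorbate, the surface hydroxyls, the framework, and frozen terminal
#' hydrogens.
#'
#' @param elements character vector of element symbols
#' @param xyz numeric N x 3 matrix of Cartesian coordinates, Angstrom
#' @param cell optional 2D lattice as c(a, b, gamma): lengths in Angstrom,
#'   angle in degrees
#' @param roles per-atom tags from \code{c("adsorbate", "silanol",
#'   "framework", "terminal_H")}; defaults to "framework"
#' @return an object of class \code{structure3d}
#' @export
structure3d <- function(elements, xyz, cell = NULL, roles = NULL) {
  xyz <- as.matrix(xyz)
  if (length(elements) == 0L) stop("structure must contain at least one atom")
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3L)
    stop("xyz must be an N x 3 matrix matching 'elements'")
  if (!all(is.finite(xyz))) stop("atomic positions must be finite")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 3L || cell[1] <= 0 || cell[2] <= 0 ||
        cell[3] <= 0 || cell[3] >= 180)
      stop("cell must be c(a > 0, b > 0, 0 < gamma < 180)")
  }
  if (is.null(roles)) roles <- rep("framework", length(elements))
  roles <- match.arg(roles, .ROLES, several.ok = TRUE)
  if (length(roles) != length(elements))
    stop("every atom needs exactly one role tag")
  out <- list(elements = as.character(elements), xyz = unname(xyz),
              cell = cell, roles = roles)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms (%s)\n", length(x$elements),
              paste(unique(x$elements), collapse = " ")))
  if (!is.null(x$cell))
    cat(sprintf("  2D cell: a = %.3f A, b = %.3f A, gamma = %.2f deg\n",
                x$cell[1], x$cell[2], x$cell[3]))
  invisible(x)
}

# elements with tabulated masses / recognised symbols
.ELEMENT_MASS <- c(H = 1.00794, C = 12.011, N = 14.007, O = 15.999,
                   Si = 28.0855, F = 18.998, Cl = 35.453, S = 32.06,
                   P = 30.974, Ar = 39.948, He = 4.0026, Ne = 20.180)

#' Read a structure from an (extended) XYZ file
#'
#' The comment line may carry 2D slab lattice metadata as three numbers
#' \code{"a b gamma"} (optionally prefixed with \code{cell:}) and atoms may
#' carry a trailing role tag as a 5th column.
#'
#' @param path path to an XYZ file
#' @return a [structure3d()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("not an XYZ file (fewer than 2 lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ line 1 must be the atom count")
  if (n < 1L) stop("structures must be non-empty")
  if (length(lines) < 2L + n) stop("XYZ declares ", n, " atoms but file is shorter")
  cell <- .parse_cell_comment(lines[2])
  elements <- character(n); xyz <- matrix(NA_real_, n, 3); roles <- rep("framework", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[2L + i]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop("malformed atom line ", 2L + i, ": '", lines[2L + i], "'")
    coords <- suppressWarnings(as.numeric(.normalize_minus(tok[2:4])))
    if (any(is.na(coords)))
      stop("malformed atom line ", 2L + i, ": non-numeric coordinate")
    if (!tok[1] %in% names(.ELEMENT_MASS))
      stop("unknown element symbol '", tok[1], "' on line ", 2L + i)
    elements[i] <- tok[1]; xyz[i, ] <- coords
    if (length(tok) >= 5L && tok[5] %in% .ROLES) roles[i] <- tok[5]
  }
  structure3d(elements, xyz, cell = cell, roles = roles)
}

.parse_cell_comment <- function(comment) {
  m <- regmatches(comment, gregexpr("[-+−]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",
                                    comment))[[1]]
  if (length(m) < 3L) return(NULL)
  as.numeric(.normalize_minus(m[1:3]))
}

#' Write a structure to an XYZ file
#'
#' Inverse of [read_xyz()]: cell metadata goes on the comment line, role tags
#' in a 5th column.
#'
#' @param s a [structure3d()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_xyz <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  comment <- if (!is.null(s$cell))
    sprintf("cell: %.10g %.10g %.10g", s$cell[1], s$cell[2], s$cell[3]) else ""
  body <- vapply(seq_along(s$elements), function(i)
    sprintf("%-2s %18.10f %18.10f %18.10f %s", s$elements[i],
            s$xyz[i, 1], s$xyz[i, 2], s$xyz[i, 3], s$roles[i]),
    character(1))
  writeLines(c(length(s$elements), comment, body), path)
  invisible(path)
}

# the printed tables use U+2212 for negative values
.normalize_minus <- function(x) gsub("−", "-", x)

#' Read an adduct energy table
#'
#' Parses a CSV ledger of counterpoise-corrected adduct energetics with
#' columns \code{name, coverage, topology, dE_c, dE_disp, dH_c, dG_c}
#' (kJ mol\eqn{^{-1}}). The dispersion component may alternatively be given
#' as a parenthetical inside the \code{dE_c} column, the layout used when
#' such tables are printed: \code{"-80.5 (-27.4)"}. Unicode minus signs are
#' accepted.
#'
#' @param path CSV path
#' @return data.frame of class \code{adduct_energetics} with numeric energy
#'   columns; \code{dE_disp} is \code{NA} where unavailable
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (!"name" %in% names(df)) stop("energy table needs a 'name' column")
  if (!"dG_c" %in% names(df))
    stop("energy table is missing the dG_c column; Boltzmann populations ",
         "cannot be computed without Gibbs energies")
  if (!"dE_c" %in% names(df)) stop("energy table is missing the dE_c column")
  raw_dE <- .normalize_minus(as.character(df$dE_c))
  paren <- regmatches(raw_dE, regexpr("\\(([^)]*)\\)", raw_dE))
  has_paren <- lengths(regmatches(raw_dE, gregexpr("\\(", raw_dE))) > 0
  dE_c <- .num_or_stop(gsub("\\(.*\\)", "", raw_dE), df$name, "dE_c")
  dE_disp <- rep(NA_real_, nrow(df))
  if (any(has_paren)) {
    inner <- trimws(gsub("[()]", "", paren))
    dE_disp[has_paren] <- .num_or_stop(inner, df$name[has_paren], "dE_disp")
  } else if ("dE_disp" %in% names(df)) {
    raw <- trimws(.normalize_minus(as.character(df$dE_disp)))
    ok <- !(is.na(raw) | raw == "")
    dE_disp[ok] <- .num_or_stop(raw[ok], df$name[ok], "dE_disp")
  }
  out <- data.frame(
    name = as.character(df$name),
    coverage = if ("coverage" %in% names(df)) as.character(df$coverage) else NA_character_,
    topology = if ("topology" %in% names(df)) as.character(df$topology) else NA_character_,
    dE_c = dE_c, dE_disp = dE_disp,
    dH_c = .num_or_stop(.normalize_minus(as.character(df$dH_c)), df$name, "dH_c"),
    dG_c = .num_or_stop(.normalize_minus(as.character(df$dG_c)), df$name, "dG_c"),
    stringsAsFactors = FALSE)
  class(out) <- c("adduct_energetics", "data.frame")
  out
}

.num_or_stop <- function(x, labels, col) {
  v <- suppressWarnings(as.numeric(trimws(x)))
  bad <- is.na(v) & !is.na(x)
  if (any(bad))
    stop("non-numeric ", col, " for row '", labels[which(bad)[1]], "'")
  if (any(!is.finite(v[!is.na(v)]))) stop("non-finite ", col, " value")
  v
}

#' Construct a spectrum
#'
#' @param wavenumbers strictly increasing grid after sorting, cm\eqn{^{-1}}
#' @param absorbance same length as the grid, arbitrary units
#' @param kind \code{"simulated"} or \code{"experimental"}
#' @param meta optional list of provenance metadata (fwhm, normalization
#'   reference, ...)
#' @return an object of class \code{spectrum_ir}
#' @export
spectrum_ir <- function(wavenumbers, absorbance,
                        kind = c("simulated", "experimental"), meta = list()) {
  kind <- match.arg(kind)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumber and absorbance vectors differ in length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points to define a grid")
  ord <- order(wavenumbers)
  w <- as.numeric(wavenumbers)[ord]; a <- as.numeric(absorbance)[ord]
  if (any(diff(w) <= 0))
    stop("wavenumber grid has duplicated or non-increasing values")
  out <- list(wavenumbers = w, absorbance = a, kind = kind, meta = meta)
  class(out) <- "spectrum_ir"
  out
}

#' @export
print.spectrum_ir <- function(x, ...) {
  cat(sprintf("spectrum_ir (%s): %d points, %.1f-%.1f cm^-1\n", x$kind,
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' Two-column CSV (wavenumber, absorbance; header optional) or a JCAMP-DX
#' file with an XYDATA \code{(X++(Y..Y))} or XYPOINTS block in AFFN form.
#' Points are sorted to an ascending grid regardless of file order.
#'
#' @param path input path; format sniffed from content (\code{##TITLE=} marks
#'   JCAMP-DX)
#' @param kind provenance tag, default \code{"experimental"}
#' @return a [spectrum_ir()]
#' @export
read_spectrum <- function(path, kind = "experimental") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^##", first)) .read_jcamp(path, kind) else .read_spectrum_csv(path, kind)
}

.read_spectrum_csv <- function(path, kind) {
  lines <- .normalize_minus(readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  first_num <- suppressWarnings(as.numeric(strsplit(lines[1], "[,;\t ]+")[[1]][1]))
  if (is.na(first_num)) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,;\t ]+")
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  a <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(w)) || any(is.na(a))) stop("non-numeric data in spectrum CSV: ", path)
  spectrum_ir(w, a, kind = kind)
}

.read_jcamp <- function(path, kind) {
  lines <- readLines(path, warn = FALSE)
  getfld <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xf <- suppressWarnings(as.numeric(getfld("XFACTOR"))); if (is.na(xf)) xf <- 1
  yf <- suppressWarnings(as.numeric(getfld("YFACTOR"))); if (is.na(yf)) yf <- 1
  i_xy <- grep("^##(XYDATA|XYPOINTS)=", lines)
  if (!length(i_xy)) stop("no XYDATA/XYPOINTS block in JCAMP file: ", path)
  i_end <- grep("^##END=", lines)
  i_end <- i_end[i_end > i_xy[1]][1]
  if (is.na(i_end)) i_end <- length(lines) + 1L
  body <- lines[(i_xy[1] + 1L):(i_end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (grepl("XYPOINTS", lines[i_xy[1]]) || grepl("\\(XY..XY\\)", lines[i_xy[1]])) {
    parts <- strsplit(trimws(.normalize_minus(body)), "[,;\t ]+")
    w <- as.numeric(vapply(parts, `[`, "", 1L)) * xf
    a <- as.numeric(vapply(parts, `[`, "", 2L)) * yf
    return(spectrum_ir(w, a, kind = kind))
  }
  # (X++(Y..Y)): first token of each line is X of the first Y on that line
  w <- numeric(0); a <- numeric(0)
  npts <- suppressWarnings(as.integer(getfld("NPOINTS")))
  for (ln in body) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(.normalize_minus(ln)),
                                                "[\t ]+")[[1]]))
    if (any(is.na(tok)) || length(tok) < 2L)
      stop("unsupported or malformed JCAMP data line: '", ln, "'")
    x0 <- tok[1] * xf; ys <- tok[-1] * yf
    # per-line X spacing from the following line when available
    w <- c(w, x0); a <- c(a, ys[1])
    if (length(ys) > 1L) { w <- c(w, rep(NA_real_, length(ys) - 1L)); a <- c(a, ys[-1]) }
  }
  # fill implicit abscissae by uniform interpolation between line anchors
  known <- which(!is.na(w))
  if (length(known) >= 2L) {
    w <- approx(known, w[known], xout = seq_along(w), rule = 2)$y
  } else if (!is.na(npts) && npts == length(a)) {
    lastx <- suppressWarnings(as.numeric(getfld("LASTX")))
    w <- seq(w[known], lastx, length.out = npts)
  }
  if (length(known) >= 2L && !is.na(npts) && length(a) == npts) {
    lastx <- suppressWarnings(as.numeric(getfld("LASTX")))
    if (!is.na(lastx)) {
      step <- (lastx - w[1]) / (npts - 1)
      w <- w[1] + step * (seq_len(npts) - 1L)
    }
  }
  spectrum_ir(w, a, kind = kind)
}

#' Write a spectrum as CSV or JCAMP-DX
#'
#' @param sp a [spectrum_ir()]
#' @param path output path
#' @param format \code{"csv"} or \code{"jcamp"}
#' @return \code{path}, invisibly
#' @export
write_spectrum <- function(sp, path, format = c("csv", "jcamp")) {
  stopifnot(inherits(sp, "spectrum_ir"))
  format <- match.arg(format)
  if (format == "csv") {
    writeLines(c("wavenumber,absorbance",
                 sprintf("%.10g,%.12g", sp$wavenumbers, sp$absorbance)), path)
  } else {
    hdr <- c("##TITLE=adsorbIR spectrum", "##JCAMP-DX=4.24",
             "##DATA TYPE=INFRARED SPECTRUM", "##XUNITS=1/CM",
             "##YUNITS=ABSORBANCE", "##XFACTOR=1", "##YFACTOR=1",
             sprintf("##FIRSTX=%.10g", sp$wavenumbers[1]),
             sprintf("##LASTX=%.10g", sp$wavenumbers[length(sp$wavenumbers)]),
             sprintf("##NPOINTS=%d", length(sp$wavenumbers)),
             "##XYPOINTS=(XY..XY)")
    body <- sprintf("%.10g, %.12g", sp$wavenumbers, sp$absorbance)
    writeLines(c(hdr, body, "##END="), path)
  }
  invisible(path)
}

#' Run configuration for the adduct-spectrum pipeline
#'
#' @param temperature K, default 298.15 (standard temperature)
#' @param pressure atm, default 1
#' @param fwhm Gaussian full width at half maximum, cm\eqn{^{-1}}, default 20
#' @param grid c(lo, hi, step) in cm\eqn{^{-1}}; default covers the carbonyl
#'   stretch and NH2 bend region at 0.5 cm\eqn{^{-1}} step
#' @param scale_rules list of [scale_rule()]s; default: C=O stretch window
#'   (1600, 1800) cm\eqn{^{-1}} scaled by 0.9972 and NH2 bend window
#'   (1500, 1600) cm\eqn{^{-1}} scaled by 1.0102
#' @param coverage ensemble mode, \code{"LC"} (one adsorbate per cell) or
#'   \code{"HC"} (two)
#' @param amplitude Gaussian amplitude convention, \code{"height"} or
#'   \code{"area"}
#' @return list of class \code{run_config}
#' @export
run_config <- function(temperature = 298.15, pressure = 1, fwhm = 20,
                       grid = c(1500, 1800, 0.5),
                       scale_rules = default_scale_rules(),
                       coverage = c("LC", "HC"),
                       amplitude = c("height", "area")) {
  coverage <- match.arg(coverage)
  amplitude <- match.arg(amplitude)
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (pressure <= 0) stop("pressure must be > 0 atm")
  if (fwhm <= 0) stop("fwhm must be > 0 cm^-1")
  if (length(grid) != 3L || grid[1] >= grid[2] || grid[3] <= 0)
    stop("grid must be c(lo < hi, step > 0)")
  out <- list(temperature = temperature, pressure = pressure, fwhm = fwhm,
              grid = as.numeric(grid), scale_rules = scale_rules,
              coverage = coverage, amplitude = amplitude)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; scale rules are given as a
#' list of \code{{class_label, lo, hi, factor}} records.
#'
#' @param path YAML (.yml/.yaml) or JSON file
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  rules <- if (!is.null(raw$scale_rules)) {
    rl <- raw$scale_rules
    if (is.data.frame(rl)) rl <- split(rl, seq_len(nrow(rl)))
    lapply(rl, function(r) scale_rule(r$class_label, c(r$lo, r$hi), r$factor))
  } else default_scale_rules()
  run_config(
    temperature = raw$temperature %||% 298.15,
    pressure = raw$pressure %||% 1,
    fwhm = raw$fwhm %||% 20,
    grid = if (!is.null(raw$grid)) as.numeric(unlist(raw$grid)) else c(1500, 1800, 0.5),
    scale_rules = rules,
    coverage = raw$coverage %||% "LC",
    amplitude = raw$amplitude %||% "height")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
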
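## Reading and writing HMD-style whitespace-delimited mortality text files:
## two free-text header lines, a column-header line, then one row per
## (year, age) with ages 0..109 and the open group "110+", missing values
## marked ".".

.hmdColumns <- list(
  mx_1x1 = c("Year", "Age", "mx"),
  life_table_1x1 = c("Year", "Age", "mx", "qx", "ax", "lx", "dx",
                     "Lx", "Tx", "ex")
)

#' Read an HMD-style mortality text file
#'
#' Parses a Human Mortality Database style 1x1 file: either a death-rate
#' file (\code{Mx_1x1}, columns \code{Year Age mx} at minimum) or a full
#' period/cohort life table (columns \code{Year Age mx qx ax lx dx Lx Tx
#' ex}). The first two lines are treated as a free-text header (the first
#' becomes the population label), the third line as the column header.
#' Age \code{"110+"} is parsed as the open age group; \code{"."} becomes
#' \code{NA}.
#'
#' @param path file path.
#' @param kind "mx_1x1" or "life_table_1x1".
#' @return an [HmdTable-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("Synthetic population, Mx (period 1x1)", "",
#'              " Year  Age  mx",
#'              sprintf(" 2000  %s  0.1", c(0:109, "110+"))), f)
#' readHmd(f, "mx_1x1")
#' @export
readHmd <- function(path, kind = c("mx_1x1", "life_table_1x1")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    .err("invalid_argument", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L)
    .err("parse", sprintf("%s: fewer than 4 lines; not an HMD-style file",
                          path))
  label <- trimws(lines[1L])
  header <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  need <- .hmdColumns[[kind]]
  missingCols <- setdiff(need, header)
  if (length(missingCols))
    .err("schema", sprintf("%s: missing required column(s): %s", path,
                           paste(missingCols, collapse = ", ")))
  body <- lines[-(1:3)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineNo <- (4:length(lines))[keep]
  tok <- strsplit(trimws(body), "\\s+")
  nf <- lengths(tok)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    .err("parse",
         sprintf("%s: line %d has %d fields, expected %d", path,
                 lineNo[bad], nf[bad], length(header)))
  }
  mat <- do.call(rbind, tok)
  colnames(mat) <- header
  ageRaw <- mat[, "Age"]
  open <- grepl("\\+$", ageRaw)
  age <- suppressWarnings(as.integer(sub("\\+$", "", ageRaw)))
  year <- suppressWarnings(as.integer(mat[, "Year"]))
  if (anyNA(age) || anyNA(year))
    .err("parse", sprintf("%s: non-numeric Year or Age entry", path))
  numCols <- setdiff(header, c("Year", "Age"))
  d <- data.frame(Year = year, Age = age, open = open)
  for (cc in numCols) {
    v <- mat[, cc]
    v[v == "."] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v)))
      .err("parse", sprintf("%s: non-numeric value in column %s", path, cc))
    d[[cc]] <- num
  }
  if (anyDuplicated(d[c("Year", "Age")])) {
    dup <- d[duplicated(d[c("Year", "Age")]), c("Year", "Age")][1L, ]
    .err("schema",
         sprintf("%s: duplicated (Year, Age) pair (%d, %d)", path,
                 dup$Year, dup$Age))
  }
  new("HmdTable", kind = kind, label = label, data = d)
}

#' Write an HMD-style mortality text file
#'
#' Inverse of [readHmd()]: writes the two-line header, the column header
#' and fixed-width rows. \code{NA} values are written as \code{"."} and
#' the open age group as \code{"110+"}. Finite values round-trip through
#' [readHmd()] losslessly (12 significant digits).
#'
#' @param tbl an [HmdTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeHmd <- function(tbl, path) {
  stopifnot(is(tbl, "HmdTable"))
  validObject(tbl)
  d <- tbl@data
  numCols <- setdiff(names(d), c("Year", "Age", "open"))
  ageStr <- ifelse(d$open, paste0(d$Age, "+"), as.character(d$Age))
  cols <- c(list(formatC(d$Year, width = 6),
                 formatC(ageStr, width = 6)),
            lapply(d[numCols], function(v)
              formatC(ifelse(is.na(v), ".",
                             formatC(v, digits = 12, format = "g")),
                      width = 18)))
  hdr <- paste(c(formatC("Year", width = 6), formatC("Age", width = 6),
                 formatC(numCols, width = 18)), collapse = " ")
  writeLines(c(tbl@label, "", hdr, do.call(paste, cols)), path)
  invisible(path)
}

#' Hazard schedule from an HMD table
#'
#' Extracts one year (or cohort) and converts its central death rates to a
#' hazard on a fine grid, treating \code{mx} as a piecewise-constant
#' hazard over each one-year age interval \code{[x, x+1)}; the open age
#' group extends its rate to \code{omega}. The \code{ax} column of full
#' life tables is ignored (the continuous framework works directly with
#' the force of mortality, for which \code{mx} is the standard
#' approximation). Ages with missing \code{mx} are excluded with a
#' warning; the preceding age's rate is carried forward over the gap.
#'
#' @param tbl an [HmdTable-class].
#' @param year calendar year (or cohort) to extract.
#' @param grid target [AgeGrid-class].
#' @return a [HazardSchedule-class].
#' @export
hazardFromHmd <- function(tbl, year, grid = makeAgeGrid()) {
  stopifnot(is(tbl, "HmdTable"))
  d <- tbl@data[tbl@data$Year == year, ]
  if (nrow(d) == 0L)
    .err("lookup",
         sprintf("year %s not present (file covers %d-%d)", year,
                 min(tbl@data$Year), max(tbl@data$Year)))
  d <- d[order(d$Age), ]
  if (anyNA(d$mx)) {
    warning(sprintf(
      "%d age(s) with missing mx in year %s excluded; previous age's rate carried forward",
      sum(is.na(d$mx)), year))
    if (is.na(d$mx[1L]))
      .err("undefined_value",
           sprintf("mx missing at the first age of year %s", year))
    for (i in which(is.na(d$mx))) d$mx[i] <- d$mx[i - 1L]
  }
  ## piecewise-constant lookup: age x falls in [Age_i, Age_{i+1})
  idx <- findInterval(grid@ages, d$Age)
  idx[idx < 1L] <- 1L                      # grid below first age: first rate
  mu <- d$mx[idx]
  hazardSchedule(mu, grid)
}
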
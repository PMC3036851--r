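#' Read and write genotype matrices
#'
#' Two dialects are supported. `"csv"`: rows are individuals, columns are
#' markers, header row of marker names, codes 0/1/2 with missing written as
#' `NA`. `"mapmaker_raw"`: the classic MAPMAKER/EXP raw layout for an F2
#' intercross — a `data type f2 intercross` header, a count line, then one
#' `*marker` line per marker with symbols `A` (homozygote, code 0), `H`
#' (heterozygote, 1), `B` (other homozygote, 2) and `-` (missing). Writing
#' then reading either dialect reproduces the matrix exactly.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"mapmaker_raw"`.
#' @param gm genotype matrix (integer codes 0/1/2, `NA` missing, named
#'   columns).
#' @return `read_genotypes()` returns an integer matrix of class `f2_geno`.
#' @export
read_genotypes <- function(path, dialect = c("csv", "mapmaker_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (dialect == "csv") {
    tab <- read.csv(path, check.names = FALSE)
    gm <- as.matrix(tab)
    bad <- which(!(gm %in% c(0L, 1L, 2L)) & !is.na(gm))
    if (length(bad) > 0L) {
      rc <- arrayInd(bad[1L], dim(gm))
      stop("invalid genotype code '", gm[bad[1L]], "' at row ", rc[1L],
           ", column ", rc[2L], " (", colnames(gm)[rc[2L]], ") of ", path)
    }
    storage.mode(gm) <- "integer"
    rownames(gm) <- NULL
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 3L || !grepl("^data type f2 intercross", lines[1L]))
      stop("not a MAPMAKER f2 intercross raw file: ", path)
    marker_lines <- grep("^\\*", lines)
    names <- character(0)
    rows <- list()
    code_of <- c(A = 0L, H = 1L, B = 2L)
    for (li in marker_lines) {
      parts <- strsplit(lines[li], "\\s+")[[1L]]
      nm <- sub("^\\*", "", parts[1L])
      sym <- strsplit(paste(parts[-1L], collapse = ""), "")[[1L]]
      bad <- which(!sym %in% c("A", "H", "B", "-"))
      if (length(bad) > 0L)
        stop("invalid genotype symbol '", sym[bad[1L]], "' at line ", li,
             ", individual ", bad[1L], " (marker ", nm, ") of ", path)
      codes <- unname(code_of[sym])
      codes[sym == "-"] <- NA_integer_
      names <- c(names, nm)
      rows[[length(rows) + 1L]] <- codes
    }
    lens <- lengths(rows)
    if (length(unique(lens)) > 1L)
      stop("ragged marker lines in ", path, ": individuals per marker vary (",
           paste(unique(lens), collapse = ", "), ")")
    gm <- do.call(cbind, rows)
    colnames(gm) <- names
  }
  structure(gm, class = c("f2_geno", class(gm)))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path, dialect = c("csv", "mapmaker_raw")) {
  dialect <- match.arg(dialect)
  gm <- unclass(gm)
  if (dialect == "csv") {
    df <- as.data.frame(gm)
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    sym <- c("A", "H", "B")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("data type f2 intercross", con)
    writeLines(sprintf("%d %d 0", nrow(gm), ncol(gm)), con)
    for (j in seq_len(ncol(gm))) {
      s <- ifelse(is.na(gm[, j]), "-", sym[gm[, j] + 1L])
      writeLines(sprintf("*%s %s", colnames(gm)[j], paste(s, collapse = "")),
                 con)
    }
  }
  invisible(path)
}

#' Read and write distance matrices as TSV triples
#'
#' A distance matrix is stored as up to three TSV files with identical
#' layout — a header row of marker names and a symmetric numeric body: the
#' main file holds the cM distances, and companion files with suffixes
#' `.r.tsv` and `.lod.tsv` (replacing the main `.tsv`) hold the
#' recombination-fraction and LOD matrices when present. Reading validates
#' symmetry, zero diagonal and finiteness.
#'
#' @param D a [distance_matrix()].
#' @param path path of the main (distance) TSV.
#' @return `read_distance_matrix()` returns a [distance_matrix()].
#' @export
write_distance_matrix <- function(D, path) {
  stopifnot(inherits(D, "dist_matrix"))
  write_one <- function(m, p) {
    df <- as.data.frame(m)
    colnames(df) <- D$markers
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_one(D$d, path)
  if (!is.null(D$r)) write_one(D$r, companion_path(path, "r"))
  if (!is.null(D$lod)) write_one(D$lod, companion_path(path, "lod"))
  invisible(path)
}

companion_path <- function(path, what) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", paste0(".", what, ".tsv"), path)
  else paste0(path, ".", what, ".tsv")
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("distance matrix not found: ", path)
  read_one <- function(p) {
    tab <- read.table(p, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(tab)
    if (any(!is.finite(m)))
      stop("non-finite entry in ", p)
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
      stop("matrix in ", p, " is not symmetric")
    m
  }
  d <- read_one(path)
  rp <- companion_path(path, "r")
  lp <- companion_path(path, "lod")
  distance_matrix(d,
                  r = if (file.exists(rp)) read_one(rp) else NULL,
                  lod = if (file.exists(lp)) read_one(lp) else NULL,
                  markers = colnames(d))
}
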
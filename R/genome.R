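#' Construct a genome specification for simulation
#'
#' A genome specification is the ground truth for the F2 simulator: an ordered
#' list of linkage groups, each holding marker names and their true map
#' positions in centimorgans.
#'
#' @param groups a list; each element is a list (or data.frame) with
#'   components `markers` (character, unique genome-wide) and `pos` (numeric,
#'   non-negative, strictly increasing), and optionally `name`.
#' @return an object of class `genome_spec`: a list of groups, each with
#'   `name`, `markers`, `pos` and `length` (span in cM).
#' @seealso [demo_genome()] for the built-in benchmark genome,
#'   [read_genome()] for YAML/JSON configs.
#' @examples
#' g <- genome_spec(list(list(markers = c("a", "b", "c"), pos = c(0, 10, 30))))
#' g[[1]]$length  # 30
#' @export
genome_spec <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a non-empty list")
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    gr <- groups[[i]]
    markers <- as.character(gr$markers)
    pos <- as.numeric(gr$pos)
    if (length(markers) != length(pos) || length(pos) < 1L)
      stop("group ", i, ": 'markers' and 'pos' must have equal positive length")
    if (any(!is.finite(pos)) || any(pos < 0))
      stop("group ", i, ": positions must be finite and non-negative")
    if (length(pos) > 1L && any(diff(pos) <= 0))
      stop("group ", i, ": positions must be strictly increasing")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else paste0("LG", i)
    out[[i]] <- list(name = nm, markers = markers, pos = pos,
                     length = pos[length(pos)] - pos[1L])
  }
  all_markers <- unlist(lapply(out, `[[`, "markers"))
  if (anyDuplicated(all_markers))
    stop("marker names must be unique genome-wide")
  structure(out, class = "genome_spec")
}

#' The built-in four-group benchmark genome
#'
#' Four linkage groups, each spanning exactly 100 cM, with decreasing
#' saturation: 51 markers at 2 cM spacing, 21 at 5 cM, 11 at 10 cM and 6 at
#' 20 cM (89 markers total, named `m1` ... `m89`). This is the standard
#' design for stressing orderers across saturation levels: group 1 is dense
#' enough that two-point distances from small populations become ambiguous,
#' while group 4 is trivial.
#'
#' @return a [genome_spec()] with four groups.
#' @examples
#' g <- demo_genome()
#' vapply(g, function(x) length(x$markers), 1L)  # 51 21 11 6
#' @export
demo_genome <- function() {
  sizes <- c(51L, 21L, 11L, 6L)
  spacing <- c(2, 5, 10, 20)
  first <- cumsum(c(1L, sizes))[1:4]
  groups <- lapply(1:4, function(i) {
    idx <- first[i] + seq_len(sizes[i]) - 1L
    list(name = paste0("LG", i),
         markers = paste0("m", idx),
         pos = spacing[i] * (seq_len(sizes[i]) - 1))
  })
  genome_spec(groups)
}

#' Read a genome specification from a YAML or JSON config
#'
#' The config holds a top-level `groups` list. Each group is either explicit
#' (`markers` + `pos`) or generated from `n_markers` and `spacing_cm`
#' (markers named `<name_prefix><i>` with `i` continuing across groups,
#' default prefix `"m"`).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [genome_spec()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unrecognized genome config extension: ", ext)
  )
  if (is.null(cfg$groups)) stop("genome config must have a 'groups' entry")
  next_idx <- 1L
  groups <- lapply(cfg$groups, function(gr) {
    if (!is.null(gr$markers)) return(gr)
    n <- as.integer(gr$n_markers)
    if (is.na(n) || n < 1L) stop("group needs 'markers' or 'n_markers'")
    sp <- as.numeric(gr$spacing_cm)
    prefix <- if (!is.null(gr$name_prefix)) gr$name_prefix else "m"
    out <- list(name = gr$name,
                markers = paste0(prefix, next_idx + seq_len(n) - 1L),
                pos = sp * (seq_len(n) - 1))
    next_idx <<- next_idx + n
    out
  })
  genome_spec(groups)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome specification:", length(x), "linkage group(s),",
      sum(vapply(x, function(g) length(g$markers), 1L)), "markers\n")
  for (g in x)
    cat(sprintf("  %s: %d markers spanning %.1f cM (%s ... %s)\n",
                g$name, length(g$markers), g$length,
                g$markers[1L], g$markers[length(g$markers)]))
  invisible(x)
}
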
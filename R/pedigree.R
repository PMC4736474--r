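#' Assemble and validate a pedigree
#'
#' Builds a topologically sorted pedigree from tabular records. Each record is
#' one *terminal* individual: either a founder (both parents unknown), a plain
#' offspring, or a cross followed by `selfing_generations` rounds of
#' self-fertilisation. Selfing chains are expanded internally into virtual
#' per-generation individuals so that the tabular relationship-matrix method
#' applies unchanged; only terminal individuals are exposed downstream.
#'
#' @param records A data frame with columns `id`, `parent1`, `parent2`,
#'   `selfing_generations`. Unknown parents are coded `NA`, `"0"` or `""`.
#'   `selfing_generations = 0` means the individual is the direct product of
#'   its parents (for a cross, the F1 itself); `s > 0` appends `s` selfing
#'   rounds, so a cross record with `s = 4` expands to an F1..F5 chain.
#' @return An object of class `pedigree`: the validated record tibble plus the
#'   expanded internal genealogy.
#' @examples
#' ped <- build_pedigree(tibble::tibble(
#'   id = c("P1", "P2", "RIL1"),
#'   parent1 = c(NA, NA, "P1"),
#'   parent2 = c(NA, NA, "P2"),
#'   selfing_generations = c(0, 0, 4)
#' ))
#' a_matrix(ped)["RIL1", "RIL1"] # 1.9375 for an F5 line
#' @seealso [a_matrix()], [inbreeding_after_selfing()]
#' @export
build_pedigree <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("id", "parent1", "parent2", "selfing_generations")
  if (!all(need %in% names(records))) {
    stop("pedigree records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$id <- as.character(records$id)
  records$parent1 <- .clean_parent(records$parent1)
  records$parent2 <- .clean_parent(records$parent2)
  records$selfing_generations <- as.integer(records$selfing_generations)
  if (anyNA(records$selfing_generations) ||
      any(records$selfing_generations < 0)) {
    stop("selfing_generations must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  named <- stats::na.omit(c(records$parent1, records$parent2))
  missing_parents <- setdiff(named, records$id)
  if (length(missing_parents)) {
    stop("parent id(s) not present as records: ",
         paste(missing_parents, collapse = ", "), call. = FALSE)
  }
  self_parent <- records$id == records$parent1 | records$id == records$parent2
  if (any(self_parent, na.rm = TRUE)) {
    stop("individual listed as its own parent: ",
         paste(records$id[which(self_parent)], collapse = ", "),
         call. = FALSE)
  }
  ord <- .topo_sort(records)
  records <- records[ord, ]
  expanded <- .expand_selfing(records)
  structure(
    list(records = records, expanded = expanded),
    class = "pedigree"
  )
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA")] <- NA_character_
  x
}

# Kahn's algorithm; errors with the offending ids if a cycle exists.
.topo_sort <- function(records) {
  n <- nrow(records)
  idx <- stats::setNames(seq_len(n), records$id)
  p1 <- unname(idx[records$parent1])
  p2 <- unname(idx[records$parent2])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(p1[i], p2[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree cycle involving: ",
         paste(records$id[setdiff(seq_len(n), out)], collapse = ", "),
         call. = FALSE)
  }
  out
}

# Expand selfing chains into virtual individuals. Returns a data frame over
# all internal individuals (topological order) with integer parent indices
# (0 = unknown) and a terminal flag mapping back to record ids.
.expand_selfing <- function(records) {
  ids <- character(0)
  p1 <- integer(0)
  p2 <- integer(0)
  terminal <- character(0)
  pos <- new.env(parent = emptyenv())
  push <- function(id, a, b, term) {
    ids <<- c(ids, id)
    p1 <<- c(p1, a)
    p2 <<- c(p2, b)
    terminal <<- c(terminal, term)
    assign(id, length(ids), envir = pos)
    length(ids)
  }
  at <- function(id) if (is.na(id)) 0L else get(id, envir = pos)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    s <- records$selfing_generations[i]
    a <- at(records$parent1[i])
    b <- at(records$parent2[i])
    if (s == 0L) {
      push(id, a, b, id)
    } else {
      prev <- push(paste0(id, ".S0"), a, b, NA_character_)
      if (s > 1L) {
        for (g in seq_len(s - 1L)) {
          prev <- push(paste0(id, ".S", g), prev, prev, NA_character_)
        }
      }
      push(id, prev, prev, id)
    }
  }
  data.frame(id = ids, p1 = p1, p2 = p2, terminal = terminal,
             stringsAsFactors = FALSE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x$records), " individuals (",
      sum(is.na(x$records$parent1) & is.na(x$records$parent2)), " founders, ",
      nrow(x$expanded), " internal nodes after selfing expansion)\n", sep = "")
  print(x$records, ...)
  invisible(x)
}

#' @export
format.pedigree <- function(x, ...) {
  paste0("<pedigree: ", nrow(x$records), " individuals>")
}

#' Additive numerator relationship matrix
#'
#' Computes the pedigree-expected additive relationship matrix `A` by the
#' tabular method: `a_ij = (a_i,p1 + a_i,p2) / 2` and
#' `a_ii = 1 + a_p1,p2 / 2`, with unknown parents treated as unrelated,
#' non-inbred base individuals. The recursion runs through the internally
#' expanded selfing chains, so an F5 line recorded as a cross with four
#' selfing rounds gets diagonal `1 + F = 1.9375`.
#'
#' @param ped A [build_pedigree()] object.
#' @return A symmetric positive semidefinite numeric matrix over the terminal
#'   individuals, with ids as dimnames, in the order of the input records.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ex <- ped$expanded
  n <- nrow(ex)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- ex$p1[i]
    q <- ex$p2[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      left <- if (p > 0L) A[j, p] else 0
      right <- if (q > 0L) A[j, q] else 0
      aij <- 0.5 * (left + right)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (p > 0L && q > 0L) 0.5 * A[p, q] else 0
  }
  keep <- which(!is.na(ex$terminal))
  out <- A[keep, keep, drop = FALSE]
  ord <- match(ped$records$id, ex$terminal[keep])
  out <- out[ord, ord, drop = FALSE]
  dimnames(out) <- list(ped$records$id, ped$records$id)
  out
}

#' Expected inbreeding coefficient after selfing
#'
#' For a generation label `g` (F_g, with F1 the non-inbred hybrid of
#' unrelated, non-inbred parents), the expected inbreeding coefficient under
#' repeated self-fertilisation is `F = 1 - (1/2)^(g-1)`; at F5 this is
#' 0.9375, i.e. the 93.75% expectation for a five-generation inbred line.
#'
#' @param g Integer generation label(s), `g >= 1`.
#' @return Numeric vector of inbreeding coefficients in `[0, 1)`.
#' @export
inbreeding_after_selfing <- function(g) {
  if (any(g < 1) || any(g != floor(g))) {
    stop("generation label g must be an integer >= 1 (F1 = the hybrid)",
         call. = FALSE)
  }
  1 - 0.5^(g - 1)
}

#' Read / write pedigree files
#'
#' The pedigree file is 4-column delimited text (comma or whitespace) with a
#' header line: `id, parent1, parent2, selfing_generations`; `0` or `NA`
#' denotes an unknown parent.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a [build_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  df <- if (grepl(",", first)) {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    readr::read_table(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  }
  names(df) <- c("id", "parent1", "parent2", "selfing_generations")[
    seq_len(ncol(df))]
  build_pedigree(df)
}

#' @param ped A `pedigree` object.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- ped$records
  out$parent1[is.na(out$parent1)] <- "0"
  out$parent2[is.na(out$parent2)] <- "0"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
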
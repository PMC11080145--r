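#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate arrange select distinct group_by ungroup
#'   summarise bind_rows left_join n row_number
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Sulston daughter suffixes: anterior/posterior, left/right, dorsal/ventral.
sulston_suffixes <- c("a", "p", "l", "r", "d", "v")

#' Founder cells of the main embryonic lineages
#'
#' The five somatic founder lineages conventionally used as subtree roots:
#' AB, MS, E, C and D. Cells are named in Sulston nomenclature, where each
#' daughter appends one of `a`, `p`, `l`, `r`, `d`, `v` to its parent's name
#' (e.g. `Ea` and `Ep` are the daughters of `E`).
#'
#' @format Character vector of length 5.
#' @export
lineage_roots <- function() c("AB", "MS", "E", "C", "D")

#' Derive a cell's parent name from Sulston nomenclature
#'
#' Non-root names are the parent's name plus one daughter suffix, so the
#' parent is obtained by dropping the last character. Root names have no
#' parent (`NA`).
#'
#' @param cell Character vector of Sulston cell names.
#' @param roots Character vector of root (founder) names.
#' @return Character vector of parent names, `NA` for roots.
#' @examples
#' parent_name(c("E", "Ea", "ABpl"))
#' @export
parent_name <- function(cell, roots = lineage_roots()) {
  out <- substr(cell, 1L, nchar(cell) - 1L)
  out[cell %in% roots] <- NA_character_
  out
}

validate_cell_names <- function(cells, roots = lineage_roots()) {
  cells <- unique(cells)
  if (any(!nzchar(cells))) {
    abort("Empty cell name encountered.", class = "treebic_parse_error")
  }
  non_root <- setdiff(cells, roots)
  if (length(non_root)) {
    last <- substr(non_root, nchar(non_root), nchar(non_root))
    bad <- non_root[!(last %in% sulston_suffixes)]
    # every non-root must eventually strip down to a listed root
    if (!length(bad)) {
      reaches_root <- vapply(non_root, function(nm) {
        while (!(nm %in% roots) && nchar(nm) > 1L) {
          s <- substr(nm, nchar(nm), nchar(nm))
          if (!(s %in% sulston_suffixes)) return(FALSE)
          nm <- substr(nm, 1L, nchar(nm) - 1L)
        }
        nm %in% roots
      }, logical(1))
      bad <- non_root[!reaches_root]
    }
    if (length(bad)) {
      abort(
        paste0(
          "Malformed cell name(s): ", paste(utils::head(bad, 5), collapse = ", "),
          ". Non-root names must be a listed root followed by suffixes from {",
          paste(sulston_suffixes, collapse = ","), "}."
        ),
        class = "treebic_parse_error"
      )
    }
  }
  invisible(cells)
}

#' Build a lineage tree from cell names
#'
#' Reconstructs the binary cell-division topology implied by Sulston names:
#' each non-root cell's parent is its name minus the final suffix character.
#' The returned object is a tibble with one row per cell (class
#' `lineage_tree`), carrying the parent link and the founder lineage each
#' cell belongs to.
#'
#' @param cells Character vector of cell names.
#' @param roots Founder names treated as parentless subtree roots.
#' @return A tibble of class `lineage_tree` with columns `cell`, `parent`,
#'   `root`, ordered lexicographically by cell name.
#' @examples
#' build_lineage_tree(c("E", "Ea", "Ep"))
#' @export
build_lineage_tree <- function(cells, roots = lineage_roots()) {
  cells <- sort(unique(cells))
  validate_cell_names(cells, roots)
  root_of <- function(nm) {
    hit <- roots[startsWith(nm, roots)]
    # longest matching founder prefix (roots are prefix-free by default)
    hit[which.max(nchar(hit))]
  }
  tree <- tibble(
    cell = cells,
    parent = parent_name(cells, roots),
    root = vapply(cells, root_of, character(1))
  )
  class(tree) <- c("lineage_tree", class(tree))
  tree
}

#' Validate binary-tree structure of observed cells
#'
#' Checks that within each lineage every observed non-root cell has a
#' derivable parent and that observed internal cells have exactly two
#' observed children. Complete binary structure holds for generated data;
#' real observations may truncate subtrees, in which case `strict = FALSE`
#' only checks parent derivability.
#'
#' @param tree A `lineage_tree`.
#' @param strict Require every non-leaf to have exactly two observed children.
#' @return `tree`, invisibly; aborts on violation.
#' @export
validate_lineage_tree <- function(tree, strict = FALSE) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (strict) {
    kids <- table(tree$parent[tree$parent %in% tree$cell])
    bad <- names(kids)[kids != 2L]
    if (length(bad)) {
      abort(paste0("Non-leaf cell(s) without exactly two children: ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "treebic_tree_error")
    }
  }
  invisible(tree)
}

#' List the cells of one lineage subtree
#'
#' @param tree A `lineage_tree`.
#' @param root A founder name present in `tree$root`.
#' @return Character vector of cell names in the subtree, sorted.
#' @export
subtree_cells <- function(tree, root) {
  sort(tree$cell[tree$root == root])
}
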
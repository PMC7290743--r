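#' Build a hierarchical decision key from diagnostic markers
#'
#' Greedy recursive construction of a taxonomic decision tree: at each
#' node, among the markers whose scope covers the current group set and
#' whose bipartition splits it, the most balanced split wins (ties broken
#' by position in the input marker table, so listing markers in their
#' published order reproduces the published key). Markers that induce the
#' same split as the chosen one are attached to the node as confirmation
#' markers, the first of them doubling as the fallback consulted when the
#' primary call is heterozygous or missing. Singleton group sets become
#' leaves.
#'
#' @param markers marker tibble as returned by [find_diagnostic_loci()]
#'   (columns `marker_id`, `allele_x`, `allele_y` and list-columns
#'   `scope`, `groups_x`, `groups_y`).
#' @param groups character vector of group names the key must resolve
#'   (default: union of all marker scopes).
#' @return object of class `kasp_tree`: nested nodes
#'   `list(type = "node", marker, confirmation, fallback, edges =
#'   list(X = ..., Y = ...))` with leaves `list(type = "leaf", group)`.
#' @export
build_decision_tree <- function(markers, groups = NULL) {
  check_cols(markers, c("marker_id", "scope", "groups_x", "groups_y"),
             "`markers`")
  groups <- groups %||% sort(unique(unlist(markers$scope)))
  if (length(groups) < 2) abort_fmt("need at least 2 groups to resolve")

  build <- function(current, used) {
    if (length(current) == 1) {
      return(list(type = "leaf", group = current))
    }
    cand <- purrr::keep(seq_len(nrow(markers)), function(i) {
      if (markers$marker_id[i] %in% used) return(FALSE)
      if (!all(current %in% markers$scope[[i]])) return(FALSE)
      sx <- intersect(markers$groups_x[[i]], current)
      length(sx) > 0 && length(sx) < length(current)
    })
    if (length(cand) == 0) {
      pairs <- utils::combn(sort(current), 2)
      abort_fmt(
        "groups unresolvable with given markers; indistinguishable pairs: %s",
        paste(apply(pairs, 2, paste, collapse = "|"), collapse = ", ")
      )
    }
    balance <- purrr::map_int(cand, function(i) {
      sx <- intersect(markers$groups_x[[i]], current)
      abs(2L * length(sx) - length(current))
    })
    pick <- cand[which.min(balance)] # ties: first in input order
    sx <- intersect(markers$groups_x[[pick]], current)
    sy <- setdiff(current, sx)
    # markers inducing the identical split become confirmation/fallback
    confirm <- purrr::keep(cand, function(i) {
      if (i == pick) return(FALSE)
      ci <- intersect(markers$groups_x[[i]], current)
      setequal(ci, sx) || setequal(ci, sy)
    })
    confirm_ids <- markers$marker_id[confirm]
    used2 <- c(used, markers$marker_id[pick], confirm_ids)
    list(
      type = "node",
      marker = markers$marker_id[pick],
      confirmation = confirm_ids,
      fallback = if (length(confirm_ids) > 0) confirm_ids[[1]] else NA_character_,
      edges = list(X = build(sx, used2), Y = build(sy, used2))
    )
  }

  structure(list(root = build(groups, character()), groups = groups),
            class = "kasp_tree")
}

#' @export
print.kasp_tree <- function(x, ...) {
  cat("<kasp_tree> resolving:", paste(x$groups, collapse = ", "), "\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "* ", node$group, "\n", sep = "")
    } else {
      extra <- if (length(node$confirmation) > 0) {
        sprintf(" (confirm: %s)", paste(node$confirmation, collapse = ", "))
      } else ""
      cat(pad, node$marker, extra, "\n", sep = "")
      cat(pad, " [X]\n", sep = "")
      show(node$edges$X, indent + 1)
      cat(pad, " [Y]\n", sep = "")
      show(node$edges$Y, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

# collect leaf groups of a tree
tree_leaves <- function(node) {
  if (node$type == "leaf") return(node$group)
  c(tree_leaves(node$edges$X), tree_leaves(node$edges$Y))
}

# maximum number of marker tests on any root-to-leaf path
tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$edges$X), tree_depth(node$edges$Y))
}

#' Tidy a decision tree into an edge table
#'
#' @param x a `kasp_tree`.
#' @param ... unused.
#' @return tibble with one row per tree edge: `marker`, `state`
#'   (`XX`/`YY`), `child` (marker id or `leaf:<group>`), `depth`,
#'   `confirmation`, `fallback`.
#' @export
tidy.kasp_tree <- function(x, ...) {
  walk <- function(node, depth) {
    if (node$type == "leaf") return(NULL)
    child_lab <- function(ch) {
      if (ch$type == "leaf") paste0("leaf:", ch$group) else ch$marker
    }
    here <- tibble::tibble(
      marker = node$marker,
      state = c("XX", "YY"),
      child = c(child_lab(node$edges$X), child_lab(node$edges$Y)),
      depth = depth,
      confirmation = paste(node$confirmation, collapse = ","),
      fallback = node$fallback
    )
    dplyr::bind_rows(here, walk(node$edges$X, depth + 1L),
                     walk(node$edges$Y, depth + 1L))
  }
  walk(x$root, 0L)
}
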
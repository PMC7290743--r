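#' KASP panel definition
#'
#' A `kasp_panel` bundles the diagnostic markers (with allele orientation,
#' scope and group bipartition), the hierarchical decision key built from
#' them, and assay metadata (primer sequences, genome coordinates,
#' reference-method allele labels). Panels round-trip through JSON with
#' [write_panel()] / [read_panel()].
#'
#' @param markers marker tibble: `marker_id`, `contig`, `pos`,
#'   `allele_x`, `allele_y`, list-columns `scope`, `groups_x`,
#'   `groups_y`, optional `fallback` and `metadata` (list-column).
#' @param name,version panel identifiers.
#' @param groups group names the panel resolves (default: union of
#'   scopes).
#' @param tree optional prebuilt `kasp_tree`; built greedily from
#'   `markers` (in input order) when omitted.
#' @param provenance free-form list recorded in the JSON.
#' @return object of class `kasp_panel`.
#' @export
kasp_panel <- function(markers, name = "unnamed", version = "0",
                       groups = NULL, tree = NULL, provenance = list()) {
  check_cols(markers, c("marker_id", "allele_x", "allele_y",
                        "scope", "groups_x", "groups_y"), "`markers`")
  if (anyDuplicated(markers$marker_id)) {
    abort_fmt("duplicate marker ids in panel")
  }
  groups <- groups %||% sort(unique(unlist(markers$scope)))
  tree <- tree %||% build_decision_tree(markers, groups)
  leaves <- tree_leaves(tree$root)
  if (!setequal(setdiff(leaves, c("unresolved", "non-target")), groups)) {
    abort_fmt("tree leaves do not match panel groups")
  }
  structure(
    list(name = name, version = version, groups = groups,
         markers = markers, tree = tree, provenance = provenance),
    class = "kasp_panel"
  )
}

#' @export
print.kasp_panel <- function(x, ...) {
  cat(sprintf("<kasp_panel> %s v%s: %d markers resolving %d groups\n",
              x$name, x$version, nrow(x$markers), length(x$groups)))
  cat(" markers:", paste(x$markers$marker_id, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname kasp_panel
#' @param x a `kasp_panel`.
#' @param ... unused.
#' @return `tidy.kasp_panel()` returns the marker table with scope and
#'   partition columns flattened to comma-separated strings.
#' @export
tidy.kasp_panel <- function(x, ...) {
  x$markers |>
    dplyr::mutate(
      scope = purrr::map_chr(.data$scope, paste, collapse = ","),
      groups_x = purrr::map_chr(.data$groups_x, paste, collapse = ","),
      groups_y = purrr::map_chr(.data$groups_y, paste, collapse = ",")
    ) |>
    dplyr::select(!dplyr::any_of("metadata"))
}

# one marker row (as list) by id, or NULL
panel_marker <- function(panel, id) {
  i <- match(id, panel$markers$marker_id)
  if (is.na(i)) return(NULL)
  as.list(panel$markers[i, ])
}

#' Derive a simulation spec from a panel's markers
#'
#' Turns each panel marker into a planted-locus specification for
#' [simulate_genotype_matrix()], so simulated cohorts carry exactly the
#' panel's fixed differences (locus ids equal to marker ids).
#'
#' @param panel a `kasp_panel`.
#' @return list of diagnostic-locus specs.
#' @export
diagnostic_spec_from_panel <- function(panel) {
  purrr::pmap(
    panel$markers[, c("marker_id", "contig", "pos", "allele_x", "allele_y",
                      "scope", "groups_x")],
    function(marker_id, contig, pos, allele_x, allele_y, scope, groups_x) {
      # panels without published coordinates get synthetic ones so the
      # simulated loci are still valid VCF records
      list(locus_id = marker_id,
           contig = if (is.na(contig)) paste0("ctg_", marker_id) else contig,
           pos = if (is.na(pos)) 5000L else pos,
           allele_x = allele_x, allele_y = allele_y,
           scope = scope, groups_x = groups_x)
    }
  )
}

# ---- JSON (de)serialisation ----

panel_to_list <- function(panel) {
  node_to_list <- function(node) {
    if (node$type == "leaf") return(list(leaf = node$group))
    list(marker = node$marker,
         confirmation = as.list(node$confirmation),
         fallback = node$fallback,
         edges = list(X = node_to_list(node$edges$X),
                      Y = node_to_list(node$edges$Y)))
  }
  mk <- purrr::pmap(panel$markers, function(...) {
    row <- list(...)
    row$scope <- as.list(row$scope)
    row$groups_x <- as.list(row$groups_x)
    row$groups_y <- as.list(row$groups_y)
    row
  })
  list(name = panel$name, version = panel$version,
       groups = as.list(panel$groups), markers = mk,
       tree = node_to_list(panel$tree$root),
       provenance = panel$provenance)
}

list_to_panel <- function(x) {
  list_to_node <- function(node) {
    if (!is.null(node$leaf)) return(list(type = "leaf", group = node$leaf))
    list(type = "node", marker = node$marker,
         confirmation = as.character(unlist(node$confirmation)),
         fallback = node$fallback %||% NA_character_,
         edges = list(X = list_to_node(node$edges$X),
                      Y = list_to_node(node$edges$Y)))
  }
  markers <- purrr::map_dfr(x$markers, function(m) {
    tibble::tibble(
      marker_id = m$marker_id,
      contig = m$contig %||% NA_character_,
      pos = as.integer(m$pos %||% NA_integer_),
      allele_x = m$allele_x, allele_y = m$allele_y,
      scope = list(as.character(unlist(m$scope))),
      groups_x = list(as.character(unlist(m$groups_x))),
      groups_y = list(as.character(unlist(m$groups_y))),
      fallback = m$fallback %||% NA_character_,
      metadata = list(m$metadata %||% list())
    )
  })
  groups <- as.character(unlist(x$groups))
  tree <- structure(list(root = list_to_node(x$tree), groups = groups),
                    class = "kasp_tree")
  kasp_panel(markers, name = x$name %||% "unnamed",
             version = as.character(x$version %||% "0"),
             groups = groups, tree = tree,
             provenance = x$provenance %||% list())
}

#' Read / write a panel definition as JSON
#'
#' @param panel a `kasp_panel`.
#' @param path file path.
#' @return `read_panel()` returns a `kasp_panel`; `write_panel()` its
#'   path, invisibly.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(panel_to_list(panel), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  list_to_panel(jsonlite::read_json(path))
}

#' Load the packaged six-haplogroup cassava whitefly panel
#'
#' The built-in panel distinguishes the six genome-wide SNP-defined
#' haplogroups of cassava-colonising *Bemisia tabaci* in sub-Saharan
#' Africa (SSA-ECA, SSA-WA, SSA-ESA, SSA-CA, SSA2, SSA4) with seven KASP
#' markers. BTS99-319 splits \{SSA-ECA, SSA-WA\} (A:A) from the other
#' four haplogroups (G:G) and doubles as the species gateway (it does
#' not amplify non-cassava *B. tabaci*); BTS22-762 separates SSA-ECA
#' (A:A) from SSA-WA (G:G) within that pair; BTS141 separates
#' \{SSA2, SSA4\} (T:T) from the rest (C:C), confirmed by BTS613 (the
#' complementary A:A / G:G split); BTS55-473 isolates SSA2 (T:T);
#' BTS46-203 separates SSA-ESA (A:A) from SSA-CA (G:G) with BTS1161
#' (C:C / A:A) as its fallback for heterozygous or failed calls.
#' Primer sequences, genome coordinates and the reference-method
#' (NextRAD-space) allele labels ride along as marker metadata.
#'
#' @param name panel selector; `"cassava-bemisia-v1"` (or the
#'   `builtin:`-prefixed form) is the only packaged panel.
#' @return a `kasp_panel` with 7 markers and 6 groups.
#' @export
load_canonical_panel <- function(name = "cassava-bemisia-v1") {
  name <- sub("^builtin:", "", name)
  if (name != "cassava-bemisia-v1") {
    abort_fmt("unknown builtin panel '%s'", name)
  }
  read_panel(system.file("extdata", "cassava_bemisia_v1.json",
                         package = "kaspdx", mustWork = TRUE))
}
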
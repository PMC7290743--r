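#' Classify one sample through a panel's decision key
#'
#' Walks the panel's decision tree from the root. At each node the
#' primary marker's call picks the edge (homozygous X or Y). A
#' heterozygous or missing call is referred to the node's fallback
#' marker when one exists (`used_fallback` flag); otherwise the sample
#' is `unresolved` (`missing_marker` for a missing call,
#' `inconsistent_profile` for an unexpected heterozygote). Confirmation
#' markers attached to a node are checked whenever their call is
#' present: a homozygous confirmation call pointing at the other side of
#' the split sets `confirmation_discordant` and yields `unresolved`.
#' A sample whose assay did not amplify at all (explicit
#' `amplified = FALSE`, or every marker missing when `amplified` is
#' unknown) is `non-target` - the gateway marker's amplification is a
#' species filter before any genotype logic.
#'
#' @param calls the sample's marker calls: a named character vector
#'   (names = marker ids) or a tibble with columns `marker` and `state`.
#'   States may be allele-space (`"XX"`, `"XY"`, `"YY"`, `"no_call"`) or
#'   nucleotide genotypes (`"A:A"`, `"A/G"`, `"./."`), which are
#'   translated per marker via the panel's allele orientation.
#' @param panel a [kasp_panel].
#' @param sample_id id recorded in the result (default `"sample"`).
#' @param amplified optional logical: did the gateway PCR amplify? An
#'   explicit value overrides the all-missing heuristic.
#' @return one-row tibble: `sample_id`, `assignment` (a group name,
#'   `"unresolved"` or `"non-target"`), `path` (markers consulted with
#'   their calls, `" > "`-separated) and `flags` (comma-separated subset
#'   of `used_fallback`, `confirmation_discordant`, `missing_marker`,
#'   `inconsistent_profile`).
#' @examples
#' panel <- load_canonical_panel()
#' classify_sample(c("BTS99-319" = "A:A", "BTS22-762" = "A:A"), panel)
#' @export
classify_sample <- function(calls, panel, sample_id = "sample",
                            amplified = NA) {
  states <- normalise_callset(calls, panel)
  if (length(states) == 0) abort_fmt("empty call set for sample '%s'", sample_id)

  result <- function(assignment, path, flags) {
    tibble::tibble(sample_id = sample_id, assignment = assignment,
                   path = paste(path, collapse = " > "),
                   flags = paste(sort(unique(flags)), collapse = ","))
  }
  pretty_call <- function(id, st) {
    m <- panel_marker(panel, id)
    sprintf("%s:%s", id, state_to_geno(st, m$allele_x, m$allele_y))
  }

  if (isFALSE(amplified) ||
      (is.na(amplified) && all(states == "no_call"))) {
    return(result("non-target", character(), character()))
  }

  path <- character()
  flags <- character()
  node <- panel$tree$root
  while (node$type != "leaf") {
    id <- node$marker
    s <- get_state(states, id)
    side_x <- tree_leaves(node$edges$X)
    side_y <- tree_leaves(node$edges$Y)
    chosen <- NULL

    if (s %in% c("XX", "YY")) {
      path <- c(path, pretty_call(id, s))
      chosen <- if (s == "XX") "X" else "Y"
    } else if (s %in% c("XY", "no_call")) {
      if (s == "XY") path <- c(path, pretty_call(id, s))
      fb <- node$fallback
      fs <- if (!is.na(fb)) get_state(states, fb) else "no_call"
      if (!is.na(fb) && fs %in% c("XX", "YY")) {
        side <- marker_side(panel, fb, fs, c(side_x, side_y))
        path <- c(path, pretty_call(fb, fs))
        flags <- c(flags, "used_fallback")
        if (setequal(side, side_x)) {
          chosen <- "X"
        } else if (setequal(side, side_y)) {
          chosen <- "Y"
        } else {
          return(result("unresolved", path, c(flags, "inconsistent_profile")))
        }
      } else {
        flag <- if (s == "no_call") "missing_marker" else "inconsistent_profile"
        return(result("unresolved", path, c(flags, flag)))
      }
    } else { # invalid state string
      return(result("unresolved", path, c(flags, "inconsistent_profile")))
    }

    # confirmation markers: a present, homozygous call must agree
    for (cid in setdiff(node$confirmation, path_ids(path))) {
      cs <- get_state(states, cid)
      if (cs %in% c("XX", "YY")) {
        cside <- marker_side(panel, cid, cs, c(side_x, side_y))
        agreed <- if (chosen == "X") setequal(cside, side_x) else setequal(cside, side_y)
        if (!agreed) {
          path <- c(path, pretty_call(cid, cs))
          return(result("unresolved", path,
                        c(flags, "confirmation_discordant")))
        }
      }
    }

    node <- if (chosen == "X") node$edges$X else node$edges$Y
  }
  result(node$group, path, flags)
}

# named-vector lookup defaulting to no_call
get_state <- function(states, id) {
  if (id %in% names(states)) unname(states[[id]]) else "no_call"
}

# marker ids already recorded in the path strings
path_ids <- function(path) sub(":.*$", "", path)

# groups (within `universe`) implied by a marker's homozygous state
marker_side <- function(panel, id, state, universe) {
  m <- panel_marker(panel, id)
  side <- if (state == "XX") m$groups_x[[1]] else m$groups_y[[1]]
  intersect(side, universe)
}

# calls in any accepted shape -> named state vector in XX/XY/YY space
normalise_callset <- function(calls, panel) {
  if (is.data.frame(calls)) {
    check_cols(calls, c("marker", "state"), "`calls`")
    v <- stats::setNames(as.character(calls$state), calls$marker)
  } else {
    v <- calls
  }
  if (length(v) == 0) return(character())
  if (is.null(names(v)) || any(names(v) == "")) {
    abort_fmt("calls must be named by marker id")
  }
  unknown <- setdiff(names(v), panel$markers$marker_id)
  if (length(unknown) > 0) {
    abort_fmt("call set references marker(s) not in panel: %s",
              paste(unknown, collapse = ", "))
  }
  out <- purrr::imap_chr(v, function(s, id) {
    if (s %in% c("XX", "XY", "YY", "no_call")) return(s)
    m <- panel_marker(panel, id)
    geno_to_state(s, m$allele_x, m$allele_y)
  })
  out
}

#' Classify a cohort of call sets
#'
#' Element-wise [classify_sample()] over a long call table, preserving
#' sample order of first appearance.
#'
#' @param callsets tibble with columns `sample_id`, `marker`, `state`
#'   (and optionally `amplified`, constant within sample).
#' @param panel a [kasp_panel].
#' @return tibble of classification results (class
#'   `kasp_classification`), one row per sample, with per-assignment
#'   counts available via [glance()].
#' @export
classify_cohort <- function(callsets, panel) {
  check_cols(callsets, c("sample_id", "marker", "state"), "`callsets`")
  if (nrow(callsets) == 0) {
    out <- tibble::tibble(sample_id = character(), assignment = character(),
                          path = character(), flags = character())
    return(structure(out, class = c("kasp_classification", class(out))))
  }
  if (anyDuplicated(callsets[, c("sample_id", "marker")])) {
    dup <- callsets[duplicated(callsets[, c("sample_id", "marker")]), ]
    abort_fmt("duplicate sample/marker entries: %s",
              paste(unique(dup$sample_id), collapse = ", "))
  }
  ids <- unique(callsets$sample_id)
  out <- purrr::map_dfr(ids, function(sid) {
    df <- callsets[callsets$sample_id == sid, ]
    amp <- if ("amplified" %in% names(df)) df$amplified[[1]] else NA
    classify_sample(stats::setNames(df$state, df$marker), panel,
                    sample_id = sid, amplified = amp)
  })
  structure(out, class = c("kasp_classification", class(out)))
}

#' @rdname classify_cohort
#' @param x a `kasp_classification`.
#' @param ... unused.
#' @return `glance.kasp_classification()` returns one row of
#'   per-assignment counts plus `n_total`.
#' @export
glance.kasp_classification <- function(x, ...) {
  counts <- table(factor(x$assignment,
                         levels = unique(c(sort(setdiff(unique(x$assignment),
                                                        c("unresolved", "non-target"))),
                                           "unresolved", "non-target"))))
  dplyr::bind_cols(tibble::as_tibble(t(as.matrix(counts))),
                   tibble::tibble(n_total = nrow(x)))
}
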
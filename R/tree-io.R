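#' Read and validate a time-calibrated phylogeny
#'
#' Reads a rooted Newick tree with branch lengths (expected in Myr for a
#' time-calibrated tree) and validates it for downstream comparative
#' analysis: tip labels must be unique and every edge must carry a
#' non-negative branch length. Ultrametricity is not required but can be
#' checked with [ape::is.ultrametric()].
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("Newick parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse error in '", path, "': no tree could be read",
         call. = FALSE)
  }
  validate_phylogeny(tree)
  tree
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("not a 'phylo' object", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  miss <- which(is.na(tree$edge.length))
  if (length(miss) > 0) {
    stop("missing branch length on edge(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s) present", call. = FALSE)
  }
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' Branch lengths are written with enough digits that a read/write round
#' trip preserves them to well below 1e-9.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Resolve polytomies by offsetting divergence times
#'
#' Multifurcations are resolved into a ladder of bifurcations, inserting
#' new internal edges of length `offset_myr` while shortening the edges
#' below each inserted node so that tip depths are preserved (up to
#' `offset_myr` when a child edge is shorter than the offset, in which
#' case the child edge is clamped at zero and a warning is issued).
#' Children of each polytomy are grouped left-to-right in input order, so
#' the resolution is deterministic. A binary tree is returned unchanged.
#'
#' @param tree A `phylo` object.
#' @param offset_myr Length (Myr) of each inserted internal edge; > 0.
#' @return A strictly bifurcating `phylo` object over the same taxa.
#' @export
resolve_polytomies <- function(tree, offset_myr = 1) {
  validate_phylogeny(tree)
  stopifnot(offset_myr > 0)
  # rooted convention: strictly bifurcating iff Nnode == Ntip - 1
  if (tree$Nnode == ape::Ntip(tree) - 1L) {
    return(tree)
  }
  # make zero-length internal edges explicit polytomies first, so that a
  # zero-length edge afterwards identifies an inserted node unambiguously
  tree <- ape::di2multi(tree, tol = 1e-12)
  res <- ape::multi2di(tree, random = FALSE)
  # multi2di gives the inserted subtending edges length zero, so node
  # depths are unchanged.  Record those target depths, stretch every
  # inserted edge to offset_myr, then walk the tree in preorder restoring
  # each original node's depth by adjusting its subtending edge.
  res <- stats::reorder(res, "cladewise")  # edges in preorder: parent first
  ntip <- ape::Ntip(res)
  inserted <- res$edge.length == 0 & res$edge[, 2] > ntip
  depth0 <- ape::node.depth.edgelength(res)
  root <- ntip + 1L
  depth <- rep(NA_real_, ntip + res$Nnode)
  depth[root] <- 0
  clamped <- FALSE
  for (e in seq_len(nrow(res$edge))) {
    p <- res$edge[e, 1]
    ch <- res$edge[e, 2]
    if (inserted[e]) {
      res$edge.length[e] <- offset_myr
    } else {
      len <- depth0[ch] - depth[p]
      if (len < 0) {
        clamped <- TRUE
        len <- 0
      }
      res$edge.length[e] <- len
    }
    depth[ch] <- depth[p] + res$edge.length[e]
  }
  if (clamped) {
    warning("some edges were shorter than the accumulated offset; ",
            "clamped at zero (tip depths shifted by < offset_myr)",
            call. = FALSE)
  }
  res
}

#' The 15 bioclimatic covariate columns used by the correlate analysis
#'
#' Column names for the bioclim summary variables: annual mean temperature,
#' mean diurnal range, isothermality, temperature seasonality, annual
#' temperature range, mean temperatures of the wettest/driest/warmest/
#' coldest quarters, annual precipitation, precipitation seasonality and
#' precipitation of the wettest/driest/warmest/coldest quarters.
#'
#' @return Character vector of 15 column names.
#' @export
bioclim_vars <- function() {
  c("annual_mean_temp", "diurnal_range", "isothermality",
    "temp_seasonality", "annual_temp_range",
    "temp_wettest_q", "temp_driest_q", "temp_warmest_q", "temp_coldest_q",
    "annual_precip", "precip_seasonality",
    "precip_wettest_q", "precip_driest_q",
    "precip_warmest_q", "precip_coldest_q")
}

#' Read and validate a species trait table
#'
#' Expects a delimited text file (comma or tab separated, header row) with
#' at least `species` and `dry_mass_mg` columns; recognised optional
#' columns are `smr_t`, `t_measure_c`, `status` (native/weed/crop),
#' `climate_class`, `gmax`, `t50` and the [bioclim_vars()] covariates.
#' Missing optional fields propagate as `NA` and are dropped (with counts
#' reported) by the analyses that need them.
#'
#' @param path Path to the file.
#' @param tree Optional `phylo`; if given, every species must be a tip and
#'   rows are reordered to match the tip order.
#' @return A validated `data.frame`, one row per species.
#' @export
read_trait_table <- function(path, tree = NULL) {
  if (!file.exists(path)) {
    stop("trait table not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_trait_table(tab, tree = tree)
}

#' Validate an in-memory trait table
#'
#' @param tab A data.frame as described in [read_trait_table()].
#' @param tree Optional `phylo` used to check and order the species set.
#' @return The validated (and possibly reordered) data.frame.
#' @export
validate_trait_table <- function(tab, tree = NULL) {
  req <- c("species", "dry_mass_mg")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("trait table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$species)) {
    stop("duplicate species rows: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "),
         call. = FALSE)
  }
  mass <- suppressWarnings(as.numeric(tab$dry_mass_mg))
  bad <- which(is.na(mass) | mass <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-numeric dry_mass_mg in row(s) ",
         paste(bad, collapse = ", "), " (species ",
         paste(tab$species[bad], collapse = ", "), ")", call. = FALSE)
  }
  tab$dry_mass_mg <- mass
  if ("smr_t" %in% names(tab)) {
    v <- suppressWarnings(as.numeric(tab$smr_t))
    bad <- which(!is.na(tab$smr_t) & (is.na(v) | v < 0))
    if (length(bad) > 0) {
      stop("negative or non-numeric smr_t in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab$smr_t <- v
  }
  if ("gmax" %in% names(tab)) {
    v <- suppressWarnings(as.numeric(tab$gmax))
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad) > 0) {
      stop("gmax outside [0, 100] in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab$gmax <- v
  }
  if (!is.null(tree)) {
    absent <- setdiff(tab$species, tree$tip.label)
    if (length(absent) > 0) {
      stop("species absent from tree: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    tab <- tab[match(intersect(tree$tip.label, tab$species), tab$species), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Read a raw respirometry trace table
#'
#' One row per measurement; columns `chamber_id`, `species`, `time_h`,
#' `po2_kpa`, `volume_ul`, `n_seeds`, `temp_c`, and optionally `pco2_kpa`
#' and `pressure_kpa` (defaults to 101.325 kPa when absent). Times must be
#' strictly increasing and pO2 positive within each chamber.
#'
#' @param path Path to a comma- or tab-separated file with a header row.
#' @return A validated `data.frame`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tr <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_traces(tr)
}

#' @rdname read_traces
#' @param traces An in-memory trace data.frame.
#' @export
validate_traces <- function(traces) {
  req <- c("chamber_id", "species", "time_h", "po2_kpa",
           "volume_ul", "n_seeds", "temp_c")
  miss <- setdiff(req, names(traces))
  if (length(miss) > 0) {
    stop("trace table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"pressure_kpa" %in% names(traces)) traces$pressure_kpa <- 101.325
  if (any(traces$po2_kpa <= 0)) {
    stop("non-positive po2_kpa values present", call. = FALSE)
  }
  if (any(traces$n_seeds < 1) || any(traces$volume_ul <= 0)) {
    stop("chambers must have n_seeds >= 1 and volume_ul > 0", call. = FALSE)
  }
  for (id in unique(traces$chamber_id)) {
    tt <- traces$time_h[traces$chamber_id == id]
    if (any(diff(tt) <= 0)) {
      stop("times not strictly increasing in chamber ", id, call. = FALSE)
    }
  }
  traces
}
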
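#' Atom selection specification
#'
#' A declarative atom filter.  All supplied criteria must hold
#' (intersection).  Resolution is deterministic: the matching atom
#' indices are returned sorted.
#'
#' @param chains optional character vector of chain ids.
#' @param res_range optional inclusive residue range `c(lo, hi)`, or a
#'   list of such ranges (their union).
#' @param resids optional explicit residue-id vector (union with
#'   `res_range` if both given).
#' @param atom_names optional atom-name set.
#' @param backbone_only if TRUE restrict to backbone atoms CA, C, N, O.
#' @return an object of class `cg_selection`.
#' @export
cg_selection <- function(chains = NULL, res_range = NULL, resids = NULL,
                         atom_names = NULL, backbone_only = FALSE) {
  if (!is.null(res_range) && !is.list(res_range)) res_range <- list(res_range)
  if (!is.null(res_range)) {
    for (r in res_range) {
      if (length(r) != 2L || r[2L] < r[1L])
        stop("res_range entries must be c(lo, hi) with hi >= lo")
    }
  }
  structure(list(chains = chains, res_range = res_range, resids = resids,
                 atom_names = atom_names, backbone_only = isTRUE(backbone_only)),
            class = "cg_selection")
}

#' Backbone atom names used by `backbone_only` selections
#' @return character vector `c("CA","C","N","O")`.
#' @export
backbone_names <- function() c("CA", "C", "N", "O")

#' Resolve a selection against a structure
#'
#' @param structure a `cg_structure`.
#' @param spec a [cg_selection()] (NULL selects every atom).
#' @return sorted integer vector of atom indices.  An empty result is
#'   allowed but raised as a warning, and carries `attr(, "status") ==
#'   "empty"`.
#' @export
resolve_selection <- function(structure, spec = NULL) {
  stopifnot(inherits(structure, "cg_structure"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "cg_selection"))
    if (!is.null(spec$chains)) keep <- keep & a$chain %in% spec$chains
    if (!is.null(spec$res_range) || !is.null(spec$resids)) {
      in_res <- rep(FALSE, nrow(a))
      for (r in spec$res_range)
        in_res <- in_res | (a$resid >= r[1L] & a$resid <= r[2L])
      if (!is.null(spec$resids)) in_res <- in_res | a$resid %in% spec$resids
      keep <- keep & in_res
    }
    if (!is.null(spec$atom_names)) keep <- keep & a$name %in% spec$atom_names
    if (spec$backbone_only) keep <- keep & a$name %in% backbone_names()
  }
  idx <- sort(which(keep))
  if (length(idx) == 0L) {
    warning("selection matched no atoms")
    attr(idx, "status") <- "empty"
  }
  idx
}

#' Domain definition
#'
#' Named residue range(s) constituting a structural domain (PAS, TMD,
#' CNBD, the hinges linking them, S6, or any custom region).  Ranges may
#' be given once (applied to every chain) or per chain.
#'
#' @param name domain name.
#' @param res_range inclusive range `c(lo, hi)`, a list of ranges, or a
#'   named list mapping chain id to range(s).
#' @param chains optional chain subset the domain lives on.
#' @return an object of class `cg_domain`.
#' @export
cg_domain <- function(name, res_range, chains = NULL) {
  per_chain <- is.list(res_range) && !is.null(names(res_range)) &&
    all(nzchar(names(res_range)))
  if (!per_chain && !is.list(res_range)) res_range <- list(res_range)
  ranges <- if (per_chain) res_range else NULL
  shared <- if (per_chain) NULL else res_range
  for (r in c(unlist(ranges, recursive = FALSE), shared)) {
    if (length(r) != 2L || r[2L] < r[1L]) stop("invalid residue range in domain ", name)
  }
  structure(list(name = name, ranges = ranges, shared = shared, chains = chains),
            class = "cg_domain")
}

#' Selection for a domain, optionally restricted to one chain
#' @param dom a `cg_domain`.
#' @param chain optional chain id.
#' @param backbone_only restrict to backbone atoms.
#' @return a [cg_selection()].
#' @export
domain_selection <- function(dom, chain = NULL, backbone_only = FALSE) {
  stopifnot(inherits(dom, "cg_domain"))
  rr <- if (!is.null(dom$ranges)) {
    if (is.null(chain)) unlist(unname(dom$ranges), recursive = FALSE)
    else dom$ranges[[chain]]
  } else dom$shared
  if (is.null(rr)) stop("domain ", dom$name, " has no range for chain ", chain)
  if (!is.list(rr)) rr <- list(rr)
  ch <- if (!is.null(chain)) chain else dom$chains
  cg_selection(chains = ch, res_range = rr, backbone_only = backbone_only)
}

#' Check that a hinge does not overlap the domains it links
#'
#' @param hinge,dom_a,dom_b `cg_domain` objects.
#' @return TRUE invisibly; error describing the overlap otherwise.
#' @export
check_domain_disjoint <- function(hinge, dom_a, dom_b) {
  rngs <- function(d) {
    rr <- if (!is.null(d$ranges)) unlist(unname(d$ranges), recursive = FALSE)
          else d$shared
    if (!is.list(rr)) list(rr) else rr
  }
  overlap <- function(x, y) x[1L] <= y[2L] && y[1L] <= x[2L]
  for (other in list(dom_a, dom_b)) {
    for (h in rngs(hinge)) for (o in rngs(other)) {
      if (overlap(h, o))
        stop("hinge ", hinge$name, " [", h[1L], "-", h[2L],
             "] overlaps domain ", other$name, " [", o[1L], "-", o[2L], "]")
    }
  }
  invisible(TRUE)
}
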
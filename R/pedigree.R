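#' Read a pedigree edge list
#'
#' Reads a tab-separated edge list with columns \code{relation}, \code{id1},
#' \code{id2} and relation values \code{parent_offspring} (id1 is the parent),
#' \code{full_sibling}, \code{twin} (unordered) and \code{grandparent}
#' (id1 is the grandparent).
#'
#' @param path path to the TSV file.
#' @return an object of class \code{pedigree}.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("relation", "id1", "id2") %in% names(d)))
    stop("pedigree file needs columns relation, id1, id2")
  bad <- setdiff(d$relation, c("parent_offspring", "full_sibling", "twin", "grandparent"))
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "))
  pedigree(
    parent_offspring = d[d$relation == "parent_offspring", c("id1", "id2")],
    full_sibling = d[d$relation == "full_sibling", c("id1", "id2")],
    twins = d[d$relation == "twin", c("id1", "id2")],
    grandparent = d[d$relation == "grandparent", c("id1", "id2")]
  )
}

#' Construct a pedigree
#'
#' @param parent_offspring two-column data.frame (parent, offspring).
#' @param full_sibling two-column data.frame of explicitly recorded full-sib
#'   pairs; pairs sharing a recorded parent are derived automatically and need
#'   not be listed.
#' @param twins two-column data.frame of twin pairs (unordered).
#' @param grandparent two-column data.frame (grandparent, grandchild).
#' @return an object of class \code{pedigree}.
#' @export
pedigree <- function(parent_offspring = NULL, full_sibling = NULL,
                     twins = NULL, grandparent = NULL) {
  fix <- function(d, nms) {
    if (is.null(d) || !nrow(d))
      return(stats::setNames(data.frame(a = character(), b = character(),
                                        stringsAsFactors = FALSE), nms))
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    stats::setNames(d[, 1:2], nms)
  }
  ped <- structure(list(
    parent_offspring = fix(parent_offspring, c("parent", "offspring")),
    full_sibling = fix(full_sibling, c("id1", "id2")),
    twins = fix(twins, c("id1", "id2")),
    grandparent = fix(grandparent, c("grandparent", "grandchild"))
  ), class = "pedigree")
  .check_acyclic(ped)
  ped
}

# parent -> offspring edges must not close a cycle (nobody is its own ancestor)
.check_acyclic <- function(ped) {
  e <- ped$parent_offspring
  if (!nrow(e)) return(invisible(TRUE))
  ids <- unique(c(e$parent, e$offspring))
  reach <- stats::setNames(lapply(ids, function(i) e$offspring[e$parent == i]), ids)
  for (start in ids) {
    seen <- character(); frontier <- reach[[start]]
    while (length(frontier)) {
      if (start %in% frontier) stop("pedigree cycle: ", start, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(reach[intersect(frontier, ids)])), seen)
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$parent_offspring), "parent-offspring edges,",
      nrow(x$twins), "twin pairs,", nrow(x$grandparent), "grandparent edges\n")
  invisible(x)
}

#' All sample ids referenced by a pedigree
#' @param ped a \code{pedigree}.
#' @return character vector of ids.
#' @export
pedigree_ids <- function(ped)
  unique(unlist(lapply(ped, function(d) unlist(d, use.names = FALSE))))

#' Full-sibling pairs implied by a pedigree
#'
#' Pairs sharing at least one recorded parent, merged with explicitly recorded
#' \code{full_sibling} edges.
#'
#' @param ped a \code{pedigree}.
#' @return two-column data.frame of unordered pairs.
#' @export
full_sibling_pairs <- function(ped) {
  po <- ped$parent_offspring
  derived <- list()
  for (p in unique(po$parent)) {
    kids <- sort(unique(po$offspring[po$parent == p]))
    if (length(kids) >= 2) {
      cmb <- utils::combn(kids, 2)
      derived[[p]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                                 stringsAsFactors = FALSE)
    }
  }
  out <- rbind(do.call(rbind, unname(derived)), ped$full_sibling)
  if (is.null(out) || !nrow(out))
    return(data.frame(id1 = character(), id2 = character(), stringsAsFactors = FALSE))
  key <- apply(out, 1, function(r) paste(sort(r), collapse = "\r"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The bundled pedigree of the 12 crane families
#'
#' Parent-offspring, twin and grandparent relations of the kin table, as read
#' from the banding records: 25 parent-offspring pairs, two twin pairs and four
#' grandparent-grandchild pairs.
#'
#' @return a \code{pedigree}.
#' @export
crane_pedigree <- function() {
  read_pedigree(system.file("extdata", "pedigree_kin.tsv",
                            package = "indelpop", mustWork = TRUE))
}
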
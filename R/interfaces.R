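## Inter-subunit contact mapping and death-fold interface classification.
##
## Death-fold filaments are stabilised by three conserved interface types
## (I, II, III), each made of an "a" and a "b" half-surface. Contacts are
## residue pairs whose minimum heavy-atom distance falls under a cutoff
## (default 4.5 A, the standard contact criterion; the study prints none).

#' Canonical RIP2-CARD interface patches
#'
#' The six published surface patches, full-length RIP2 numbering:
#' Ia = \{R444, E445, D492\}; Ib = \{Q458, D461, K471, Y474\};
#' IIa = \{D467, E472, D495, Q497\}; IIb = \{N449, T452, K513\};
#' IIIa = \{K471, E472, E475, T479\}; IIIb = \{T482, R483, T484, R488\}.
#' K471 and E472 each belong to two patches.
#'
#' @return Named list patch name -> integer residue numbers.
#' @export
rip2_patches <- function() {
  list(Ia = c(444L, 445L, 492L),
       Ib = c(458L, 461L, 471L, 474L),
       IIa = c(495L, 497L, 472L, 467L),
       IIb = c(449L, 452L, 513L),
       IIIa = c(479L, 475L, 471L, 472L),
       IIIb = c(483L, 482L, 484L, 488L))
}

## patch membership: residue -> character vector of patch names
patch_membership <- function(patches) {
  res <- sort(unique(unlist(patches)))
  stats::setNames(lapply(res, function(r) {
    names(patches)[vapply(patches, function(p) r %in% p, TRUE)]
  }), as.character(res))
}

PAIRINGS <- list(I = c("Ia", "Ib"), II = c("IIa", "IIb"), III = c("IIIa", "IIIb"))

#' Find inter-subunit residue contacts in a filament
#'
#' All residue pairs in distinct subunits whose minimum heavy-atom
#' distance is at most `cutoff`. Intra-subunit pairs are excluded; each
#' pair is reported once with `subunit_i < subunit_j`. Patch columns are
#' filled from the filament monomer's patch labels when present.
#'
#' @param filament a `filament_model` with >= 2 subunits (a single subunit
#'   yields an empty table).
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @return data.frame with columns subunit_i, subunit_j, residue_i,
#'   residue_j, min_dist, patch_i, patch_j.
#' @export
find_contacts <- function(filament, cutoff = 4.5) {
  stopifnot(inherits(filament, "filament_model"))
  if (cutoff <= 0) stop("cutoff must be positive")
  labels <- if (!is.null(filament$monomer)) filament$monomer$patch_labels
  lab_of <- function(res) {
    if (is.null(labels)) return(rep(NA_character_, length(res)))
    out <- unname(labels[as.character(res)])
    as.character(out)
  }
  subs <- filament$subunits
  heavy <- lapply(subs, function(s) s$atoms[s$atoms$is_heavy, , drop = FALSE])
  zr <- t(vapply(heavy, function(a) range(a$z), numeric(2L)))
  out <- list()
  ns <- length(subs)
  if (ns >= 2L) for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    if (zr[j, 1L] - zr[i, 2L] > cutoff || zr[i, 1L] - zr[j, 2L] > cutoff) next
    ai <- heavy[[i]]; aj <- heavy[[j]]
    pi_ <- atom_xyz(ai); pj <- atom_xyz(aj)
    d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") - 2 * pi_ %*% t(pj)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    df <- data.frame(residue_i = ai$resno[hit[, 1L]],
                     residue_j = aj$resno[hit[, 2L]],
                     d = sqrt(pmax(d2[hit], 0)))
    agg <- stats::aggregate(d ~ residue_i + residue_j, df, min)
    out[[length(out) + 1L]] <-
      data.frame(subunit_i = subs[[i]]$index, subunit_j = subs[[j]]$index,
                 residue_i = agg$residue_i, residue_j = agg$residue_j,
                 min_dist = agg$d,
                 patch_i = lab_of(agg$residue_i),
                 patch_j = lab_of(agg$residue_j),
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(subunit_i = integer(), subunit_j = integer(),
                      residue_i = integer(), residue_j = integer(),
                      min_dist = numeric(), patch_i = character(),
                      patch_j = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify one subunit-pair interface
#'
#' Each contact votes for the interface type whose (a, b) patch pairing it
#' matches, order-insensitively: (Ia, Ib) -> I, (IIa, IIb) -> II,
#' (IIIa, IIIb) -> III. Residues belonging to two patches (K471, E472 in
#' the canonical set) vote for whichever pairing matches the partner; if
#' both match, the contact contributes half a vote to each. The majority
#' type is assigned when its support (votes / contacts) reaches 0.5,
#' otherwise the pair is unclassified; ties break towards the type with
#' the smaller summed contact distance.
#'
#' @param contacts contact rows (from [find_contacts()]) for one subunit
#'   pair; must be non-empty.
#' @param patches named list patch -> residues (e.g. [rip2_patches()]), or
#'   NULL to use the `patch_i`/`patch_j` columns already on the contacts.
#' @return An object of class `interface_classification`: list(subunits,
#'   assigned_type, support, votes, evidence).
#' @export
classify_interface <- function(contacts, patches = NULL) {
  if (!is.data.frame(contacts) || nrow(contacts) == 0L)
    stop("contact list is empty; nothing to classify")
  if (length(unique(paste(contacts$subunit_i, contacts$subunit_j))) > 1L)
    stop("classify_interface expects contacts of a single subunit pair")
  memb <- if (!is.null(patches)) patch_membership(patches)
  side_patches <- function(res, given) {
    if (!is.null(memb)) {
      p <- memb[[as.character(res)]]
      if (is.null(p)) character(0) else p
    } else if (!is.na(given)) strsplit(given, "|", fixed = TRUE)[[1L]]
    else character(0)
  }
  votes <- c(I = 0, II = 0, III = 0)
  dist_by_type <- c(I = 0, II = 0, III = 0)
  n <- nrow(contacts)
  for (r in seq_len(n)) {
    pi_ <- side_patches(contacts$residue_i[r], contacts$patch_i[r])
    pj <- side_patches(contacts$residue_j[r], contacts$patch_j[r])
    hits <- names(PAIRINGS)[vapply(PAIRINGS, function(pp) {
      (pp[1L] %in% pi_ && pp[2L] %in% pj) || (pp[2L] %in% pi_ && pp[1L] %in% pj)
    }, TRUE)]
    if (length(hits) == 0L) next
    wt <- 1 / length(hits)
    for (h in hits) {
      votes[h] <- votes[h] + wt
      dist_by_type[h] <- dist_by_type[h] + contacts$min_dist[r]
    }
  }
  best <- names(votes)[votes == max(votes)]
  if (length(best) > 1L && max(votes) > 0)
    best <- best[which.min(dist_by_type[best])]
  best <- best[1L]
  support <- unname(votes[best]) / n
  assigned <- if (max(votes) > 0 && support >= 0.5) best else "unclassified"
  structure(list(subunits = c(contacts$subunit_i[1L], contacts$subunit_j[1L]),
                 assigned_type = assigned,
                 support = support,
                 votes = votes,
                 evidence = contacts),
            class = "interface_classification")
}

#' @export
print.interface_classification <- function(x, ...) {
  cat(sprintf("<interface_classification> subunits %d-%d: Type %s (support %.2f, %d contacts)\n",
              x$subunits[1L], x$subunits[2L], x$assigned_type, x$support,
              nrow(x$evidence)))
  invisible(x)
}

#' Classify every subunit-pair interface of a filament
#'
#' Runs [find_contacts()] and [classify_interface()] for each contacting
#' subunit pair; the lattice offset dk is reported alongside but never
#' used to force a type.
#'
#' @param filament a `filament_model`.
#' @param cutoff contact cutoff in Angstrom.
#' @param patches optional patch definition list; defaults to the labels
#'   carried on the filament's monomer.
#' @return data.frame with columns subunit_i, subunit_j, dk, assigned_type,
#'   support, n_contacts.
#' @export
classify_filament_interfaces <- function(filament, cutoff = 4.5,
                                         patches = NULL) {
  contacts <- find_contacts(filament, cutoff)
  if (nrow(contacts) == 0L)
    return(data.frame(subunit_i = integer(), subunit_j = integer(),
                      dk = integer(), assigned_type = character(),
                      support = numeric(), n_contacts = integer()))
  key <- paste(contacts$subunit_i, contacts$subunit_j)
  res <- lapply(split(contacts, key), classify_interface, patches = patches)
  out <- do.call(rbind, lapply(res, function(cl) {
    data.frame(subunit_i = cl$subunits[1L], subunit_j = cl$subunits[2L],
               dk = cl$subunits[2L] - cl$subunits[1L],
               assigned_type = cl$assigned_type, support = cl$support,
               n_contacts = nrow(cl$evidence), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subunit_i, out$subunit_j), ]
  rownames(out) <- NULL
  out
}

#' Axial surface sides of the patch set
#'
#' The fixed partition of half-surfaces into the two axial faces of a
#' subunit in the lattice: top = \{Ib, IIb\} (the activator-docking face),
#' bottom = \{Ia, IIa\}; the Type III half-surfaces are lateral.
#'
#' @param patches named list patch -> residues, default [rip2_patches()].
#' @return list with `top`, `bottom`, `lateral`, each list(patches,
#'   residues).
#' @export
surface_sides <- function(patches = rip2_patches()) {
  side <- function(nms) list(patches = nms,
                             residues = sort(unique(unlist(patches[nms]))))
  list(top = side(c("Ib", "IIb")),
       bottom = side(c("Ia", "IIa")),
       lateral = side(c("IIIa", "IIIb")))
}
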
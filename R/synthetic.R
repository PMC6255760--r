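## Synthetic pseudo-atom CARD monomer and decoys.
##
## One bead per residue (CA) plus one bead per charged side-chain terminus
## (and per bulky landmark). The monomer is a five-helix antiparallel
## bundle of ~40 x 25 x 25 A placed with its long axis tilted off the
## radial direction, so screw propagation with the RIP2 defaults yields a
## hollow-free tube of ~70-80 A diameter whose subunits touch at three
## lattice offsets: dk = 3 and dk = 4 (the two near-axial shells, used as
## the Type I and Type II interfaces) and dk = 1 (the one-start lateral
## neighbour, used as Type III).

## Run code with a private, restorable RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Lattice offsets carrying each planned interface type in the synthetic
## filament. The deposited structure does not print the dk <-> type
## mapping; this is the generator's own stated convention.
SYNTH_TYPE_OFFSETS <- c(III = 1L, I = 3L, II = 4L)

#' Specification of a synthetic CARD-like monomer
#'
#' @param bundle_dimensions target bounding box of the five-helix bundle
#'   in Angstrom, default `c(40, 25, 25)`.
#' @param centroid_radius radial distance of the monomer centroid from the
#'   filament axis once placed (Angstrom).
#' @param tilt angle (degrees) between the bundle long axis and the radial
#'   direction, tipped toward +z; makes the packing interdigitate.
#' @param first_residue first residue number (RIP2-CARD starts at 432).
#' @param params the filament symmetry the patch plan is laid out for.
#' @param patch_plan "auto" (place the six patches at the closest-approach
#'   regions of the default lattice) or a named list patch -> residue
#'   numbers; a residue may belong to at most one patch.
#' @param max_pairs_per_interface patches are built from at most this many
#'   residue pairs per interface (auto plan).
#' @param plan_cutoff inter-subunit CA-CA distance (Angstrom) under which
#'   a residue pair is eligible for the auto patch plan.
#' @param jitter per-coordinate Gaussian jitter (Angstrom) applied to the
#'   ideal bundle so the model looks molecular rather than crystalline.
#' @param seed integer; every synthetic artifact is a pure function of it.
#' @return An object of class `synthetic_monomer_spec`.
#' @export
synthetic_monomer_spec <- function(bundle_dimensions = c(40, 25, 25),
                                   centroid_radius = 17,
                                   tilt = 35,
                                   first_residue = 432L,
                                   params = rip2_params(),
                                   patch_plan = "auto",
                                   max_pairs_per_interface = 18L,
                                   plan_cutoff = 5.5,
                                   jitter = 0.15,
                                   seed = 1L) {
  stopifnot(length(bundle_dimensions) == 3L, all(bundle_dimensions > 0),
            inherits(params, "helical_params"))
  if (is.list(patch_plan)) {
    res <- unlist(patch_plan, use.names = FALSE)
    if (anyDuplicated(res))
      stop("infeasible patch_plan: two patches claim the same residue")
  } else if (!identical(patch_plan, "auto")) {
    stop("patch_plan must be \"auto\" or a named list patch -> residues")
  }
  structure(list(n_helices = 5L,
                 bundle_dimensions = as.numeric(bundle_dimensions),
                 centroid_radius = centroid_radius, tilt = tilt,
                 first_residue = as.integer(first_residue),
                 params = params, patch_plan = patch_plan,
                 max_pairs_per_interface = as.integer(max_pairs_per_interface),
                 plan_cutoff = plan_cutoff,
                 jitter = jitter, seed = as.integer(seed)),
            class = "synthetic_monomer_spec")
}

## Ideal antiparallel five-helix bundle, local frame: long axis = x.
## Returns list(xyz, resno, helix_segments).
build_bundle <- function(spec) {
  lx <- spec$bundle_dimensions[1L]
  helix_len <- max(8L, as.integer(round(lx / 1.5)) - 1L)   # residues per helix
  loop_len <- 3L
  pent_r <- spec$bundle_dimensions[2L] / 2 - 4.5           # helix-axis pentagon
  helix_r <- 2.3                                           # CA helix radius
  xyz <- NULL; resno <- integer(); segs <- list()
  nextres <- spec$first_residue
  for (h in seq_len(5L)) {
    ang <- 2 * pi * (h - 1L) / 5
    cy <- pent_r * cos(ang); cz <- pent_r * sin(ang)
    dirx <- if (h %% 2L == 1L) 1 else -1
    i <- seq_len(helix_len)
    t <- (i - (helix_len + 1) / 2) * 1.5 * dirx
    ph <- deg2rad(100 * i + 137 * h)       # per-helix phase offset
    hx <- cbind(t, cy + helix_r * cos(ph), cz + helix_r * sin(ph))
    segs[[paste0("H", h)]] <- c(nextres, nextres + helix_len - 1L)
    resno <- c(resno, seq(nextres, length.out = helix_len))
    nextres <- nextres + helix_len
    xyz <- rbind(xyz, hx)
    if (h < 5L) {
      ## straight loop between helix ends
      from <- hx[helix_len, ]
      angn <- 2 * pi * h / 5
      ton <- c(-t[helix_len],                      # next helix runs opposite
               pent_r * cos(angn) + helix_r * cos(deg2rad(100 + 137 * (h + 1))),
               pent_r * sin(angn) + helix_r * sin(deg2rad(100 + 137 * (h + 1))))
      w <- seq_len(loop_len) / (loop_len + 1)
      lp <- t(vapply(w, function(f) from + f * (ton - from), numeric(3L)))
      xyz <- rbind(xyz, lp)
      resno <- c(resno, seq(nextres, length.out = loop_len))
      nextres <- nextres + loop_len
    }
  }
  list(xyz = xyz, resno = resno, helix_segments = segs)
}

## Auto patch plan: the six patches are the contact epitopes of the mapped
## lattice offsets. Candidate residue pairs from all three shells are
## merged and greedily labelled in order of increasing distance, so a
## residue shared between two shells keeps the label of its closer
## partner. Returns data.frame(resno, patch, partner, dk, dist) with one
## row per labelled residue (the row of its closest planned pair).
plan_patches_auto <- function(xyz, resno, spec, exclude = integer()) {
  params <- spec$params
  cand <- NULL
  for (type in names(SYNTH_TYPE_OFFSETS)) {
    dk <- SYNTH_TYPE_OFFSETS[[type]]
    up <- rt_apply(screw_operator(params, dk), xyz)
    d2 <- outer(rowSums(xyz^2), rowSums(up^2), "+") - 2 * xyz %*% t(up)
    d <- sqrt(pmax(d2, 0))
    ## residue-level min distance across beads, both sides
    grp <- split(seq_along(resno), resno)
    A <- vapply(grp, function(ii) apply(d[ii, , drop = FALSE], 2L, min),
                numeric(ncol(d)))                  # beads_j x res_i
    B <- vapply(grp, function(jj) apply(A[jj, , drop = FALSE], 2L, min),
                numeric(ncol(A)))                  # res_i x res_j
    idx <- which(B <= spec$plan_cutoff, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      stop(sprintf("synthetic geometry yields no dk=%d contacts; adjust the spec", dk))
    pairs <- data.frame(ri = as.integer(rownames(B)[idx[, 1L]]),
                        rj = as.integer(colnames(B)[idx[, 2L]]),
                        dist = B[idx],
                        type = type, dk = dk, stringsAsFactors = FALSE)
    cand <- rbind(cand, pairs[order(pairs$dist), ])
  }
  cand <- cand[order(cand$dist), ]
  ## a residue may carry up to two patch labels, but only on the same
  ## half-surface side (a with a, b with b) so its formal charge stays
  ## well defined - the published patch set has such dual-membership
  ## residues (K471, E472)
  label <- list()
  can_add <- function(res, lab) {
    have <- label[[res]]
    if (is.null(have)) return(TRUE)
    if (lab %in% have) return(FALSE)     # pair already represented
    length(have) < 2L && substring(lab, nchar(lab)) ==
      substring(have[1L], nchar(have[1L]))
  }
  plan <- NULL
  taken <- stats::setNames(rep(0L, length(SYNTH_TYPE_OFFSETS)),
                           names(SYNTH_TYPE_OFFSETS))
  for (q in seq_len(nrow(cand))) {
    type <- cand$type[q]
    if (taken[[type]] >= spec$max_pairs_per_interface) next
    ri <- as.character(cand$ri[q]); rj <- as.character(cand$rj[q])
    lb <- paste0(type, "b"); la <- paste0(type, "a")
    new_i <- !lb %in% label[[ri]]; new_j <- !la %in% label[[rj]]
    ok_i <- !new_i || can_add(ri, lb)
    ok_j <- !new_j || can_add(rj, la)
    if (ri == rj || !ok_i || !ok_j || (!new_i && !new_j) ||
        cand$ri[q] %in% exclude || cand$rj[q] %in% exclude) next
    if (new_i) label[[ri]] <- c(label[[ri]], lb)
    if (new_j) label[[rj]] <- c(label[[rj]], la)
    plan <- rbind(plan, data.frame(resno = cand$ri[q], patch = lb,
                                   partner = cand$rj[q], dk = cand$dk[q],
                                   dist = cand$dist[q]),
                  data.frame(resno = cand$rj[q], patch = la,
                             partner = cand$ri[q], dk = cand$dk[q],
                             dist = cand$dist[q]))
    taken[[type]] <- taken[[type]] + 1L
  }
  short <- names(taken)[taken < 2L]
  if (length(short))
    stop(sprintf("could not place at least two residue pairs for type(s) %s",
                 paste(short, collapse = ", ")))
  plan[!duplicated(plan[, c("resno", "patch")]), , drop = FALSE]
}

#' Generate a synthetic CARD-like pseudo-atom monomer
#'
#' Deterministic for a fixed seed. The returned monomer carries helix
#' segments, patch labels (six patches Ia/Ib, IIa/IIb, IIIa/IIIb laid out
#' for the spec's helical parameters), landmark residues (three bulky
#' side chains mid-H1/H3/H5, mirroring the W439/Y474/F501 registry), and
#' charged side-chain beads: "a"-patch residues carry formal charge -1
#' (GLU-like), "b"-patch residues +1 (LYS-like), so every planned
#' cross-interface pair is an attractive salt bridge. The generating spec
#' is attached for ground-truth bookkeeping.
#'
#' @param spec a [synthetic_monomer_spec()].
#' @return A [monomer_model()].
#' @export
make_synthetic_monomer <- function(spec = synthetic_monomer_spec()) {
  stopifnot(inherits(spec, "synthetic_monomer_spec"))
  b <- build_bundle(spec)
  ## place: long axis radial tipped by tilt toward +z, centroid off-axis
  tau <- deg2rad(spec$tilt)
  Rp <- matrix(c(cos(tau), 0, sin(tau),
                 0, 1, 0,
                 -sin(tau), 0, cos(tau)), 3L, 3L, byrow = TRUE)
  xyz <- b$xyz %*% t(Rp)
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  xyz <- sweep(xyz, 2L, c(spec$centroid_radius, 0, 0), "+")
  xyz <- with_seed(spec$seed,
                   xyz + matrix(stats::rnorm(length(xyz), sd = spec$jitter),
                                ncol = 3L))
  resno <- b$resno
  ## landmarks: mid-H1, mid-H3, mid-H5 bulky residues, reserved before the
  ## patch plan so the aromatic registry never overlaps a charged patch
  landmarks <- vapply(c("H1", "H3", "H5"), function(h) {
    as.integer(round(mean(b$helix_segments[[h]])))
  }, 0L)
  ## patch plan
  if (identical(spec$patch_plan, "auto")) {
    plan <- plan_patches_auto(xyz, resno, spec, exclude = landmarks)
  } else {
    plan <- do.call(rbind, lapply(names(spec$patch_plan), function(p) {
      data.frame(resno = as.integer(spec$patch_plan[[p]]), patch = p,
                 partner = NA_integer_, dk = NA_integer_, dist = NA_real_)
    }))
  }
  plan$charge <- ifelse(grepl("a$", plan$patch), -1, 1)

  resname <- rep("ALA", length(resno))
  charge <- rep(0, length(resno))
  m <- match(resno, plan$resno)
  hit <- !is.na(m)
  resname[hit] <- ifelse(plan$charge[m[hit]] < 0, "GLU", "LYS")
  charge[hit] <- plan$charge[m[hit]]
  resname[resno %in% landmarks] <- c("TRP", "TYR", "PHE")[
    match(resno[resno %in% landmarks], landmarks)]

  atoms <- atom_table(serial = seq_along(resno), name = "CA", element = "C",
                      resno = resno, resname = resname, chain = "A",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      charge = 0)

  ## charged side-chain beads point into their planned interface
  side <- NULL
  if (any(!is.na(plan$partner))) {
    for (q in which(!is.na(plan$partner))) {
      rn <- plan$resno[q]; pn <- plan$partner[q]; dk <- plan$dk[q]
      self <- xyz[match(rn, resno), ]
      partner <- xyz[match(pn, resno), ]
      if (grepl("b$", plan$patch[q])) {            # partner sits dk above
        target <- rt_apply(screw_operator(spec$params, dk), partner)[1L, ]
      } else {                                     # partner sits dk below
        target <- rt_apply(screw_operator(spec$params, -dk), partner)[1L, ]
      }
      dvec <- target - self
      dlen <- sqrt(sum(dvec^2))
      disp <- max(0.4, (dlen - 2.8) / 2)
      pos <- self + dvec / dlen * disp
      side <- rbind(side, data.frame(resno = rn, x = pos[1L], y = pos[2L],
                                     z = pos[3L], charge = plan$charge[q]))
    }
  } else if (nrow(plan)) {
    cen <- colMeans(xyz)
    for (q in seq_len(nrow(plan))) {
      self <- xyz[match(plan$resno[q], resno), ]
      dvec <- self - cen; dvec <- dvec / sqrt(sum(dvec^2))
      pos <- self + 2 * dvec
      side <- rbind(side, data.frame(resno = plan$resno[q], x = pos[1L],
                                     y = pos[2L], z = pos[3L],
                                     charge = plan$charge[q]))
    }
  }
  if (!is.null(side)) {
    sn <- match(side$resno, resno)
    satoms <- atom_table(serial = nrow(atoms) + seq_len(nrow(side)),
                         name = ifelse(side$charge > 0, "NZ", "OE1"),
                         element = ifelse(side$charge > 0, "N", "O"),
                         resno = side$resno, resname = resname[sn],
                         chain = "A", x = side$x, y = side$y, z = side$z,
                         charge = side$charge)
    atoms <- rbind(atoms, satoms)
    atoms <- atoms[order(atoms$resno, atoms$serial), ]
    atoms$serial <- seq_len(nrow(atoms))
  }

  ## residues on two patches get a composite "X|Y" label
  labels <- vapply(split(plan$patch, plan$resno),
                   function(p) paste(unique(p), collapse = "|"), "")
  mono <- monomer_model(atoms,
                        sequence_range = range(resno),
                        helix_segments = b$helix_segments,
                        patch_labels = labels,
                        landmarks = landmarks,
                        spec = spec)
  mono$patch_plan <- plan
  mono
}

#' Permute patch labels to make a negative-control decoy
#'
#' Coordinates, charges and atom records are untouched; only the patch
#' labels are re-dealt at random among surface residues (those whose CA
#' bead lies farther from the monomer centroid than the median). Interface
#' classification on a filament of decoys should therefore fail for most
#' subunit pairs.
#'
#' @param monomer a labelled `monomer_model`.
#' @param seed integer; the permutation is a pure function of it.
#' @return A `monomer_model` with permuted `patch_labels`.
#' @export
make_patch_decoy <- function(monomer, seed) {
  stopifnot(inherits(monomer, "monomer_model"))
  if (is.null(monomer$patch_labels) || length(monomer$patch_labels) == 0L)
    stop("monomer has no patch labels to permute")
  ca <- monomer$atoms[monomer$atoms$name == "CA", , drop = FALSE]
  cen <- colMeans(atom_xyz(monomer$atoms))
  r <- sqrt((ca$x - cen[1L])^2 + (ca$y - cen[2L])^2 + (ca$z - cen[3L])^2)
  surface <- ca$resno[r >= stats::median(r)]
  surface <- union(surface, as.integer(names(monomer$patch_labels)))
  labs <- unname(monomer$patch_labels)
  new_res <- with_seed(seed, sample(surface, length(labs)))
  out <- monomer
  out$patch_labels <- stats::setNames(labs, as.character(new_res))
  out$decoy_seed <- as.integer(seed)
  out
}
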
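## Charge-reversal mutation logic for filament interfaces.
##
## A deliberately minimal model: residues carry a formal charge
## (D, E = -1; K, R = +1; everything else, including histidine, 0), a
## residue pair is attractive / repulsive / neutral by the sign of the
## charge product, and a mutant's categorical activity follows from how
## its substitutions change the native cross-interface pairs. No polar
## bonus, free energies or rotamers: the minimal model already reproduces
## the printed single/double-mutant outcomes except the D495R single
## mutant, which is recorded as a known mismatch.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Formal charge of a residue type
#'
#' D and E are -1, K and R are +1, everything else 0 (histidine included:
#' pH-dependent protonation is out of scope).
#'
#' @param code residue code(s), 1-letter or 3-letter.
#' @return Integer charge(s) in \{-1, 0, +1\}.
#' @export
residue_charge <- function(code) {
  code <- toupper(as.character(code))
  one <- ifelse(nchar(code) == 3L, unname(AA3TO1[code]), code)
  if (anyNA(one)) stop("unknown residue code")
  ifelse(one %in% c("D", "E"), -1L, ifelse(one %in% c("K", "R"), 1L, 0L))
}

#' Electrostatic category of a charge pair
#'
#' Sign of the charge product: negative = attractive, positive =
#' repulsive, zero = neutral.
#'
#' @param charge_i,charge_j formal charges in \{-1, 0, +1\}.
#' @return "attractive", "repulsive" or "neutral".
#' @export
pair_category <- function(charge_i, charge_j) {
  if (!all(c(charge_i, charge_j) %in% -1:1))
    stop("charges must be -1, 0 or +1")
  p <- charge_i * charge_j
  if (p < 0) "attractive" else if (p > 0) "repulsive" else "neutral"
}

#' Native cross-interface residue pairs of the RIP2-CARD filament
#'
#' The published pairings across the Type I and II interfaces, with
#' wild-type identities. Residue 458 is taken as arginine: the
#' charge-reversal series names the mutant R458E, and only an Arg at 458
#' makes the E445/458 single- and double-mutant outcomes internally
#' consistent under a charge model (one figure panel lists it as Q458).
#'
#' @return data.frame with columns res_i, code_i, res_j, code_j, interface.
#' @export
rip2_native_pairs <- function() {
  data.frame(res_i = c(444L, 445L, 492L, 449L, 452L, 513L),
             code_i = c("R", "E", "D", "N", "T", "K"),
             res_j = c(461L, 458L, 474L, 495L, 497L, 467L),
             code_j = c("D", "R", "Y", "D", "Q", "D"),
             interface = c("I", "I", "I", "II", "II", "II"),
             stringsAsFactors = FALSE)
}

parse_substitution <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1L]]
  if (length(m) != 4L)
    stop(sprintf("cannot parse substitution '%s' (expected e.g. 'E445R')", s))
  data.frame(site = as.integer(m[3L]), from = toupper(m[2L]),
             to = toupper(m[4L]), stringsAsFactors = FALSE)
}

#' Describe a set of point substitutions
#'
#' @param ... substitutions as strings ("E445R", "R458E", ...) and/or
#'   data.frames with columns site, from, to. The `from` code is
#'   informational only; the site number identifies the residue.
#' @return An object of class `mutant_design` (a data.frame of
#'   substitutions).
#' @export
mutant_design <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (is.data.frame(x)) x[, c("site", "from", "to")]
    else do.call(rbind, lapply(as.character(x), parse_substitution))
  })
  subs <- do.call(rbind, parts)
  if (is.null(subs)) subs <- data.frame(site = integer(), from = character(),
                                        to = character(),
                                        stringsAsFactors = FALSE)
  if (anyDuplicated(subs$site)) stop("duplicate substitution site")
  class(subs) <- c("mutant_design", "data.frame")
  subs
}

#' @export
print.mutant_design <- function(x, ...) {
  if (nrow(x) == 0L) cat("<mutant_design> wild type (no substitutions)\n")
  else cat("<mutant_design>", paste0(x$from, x$site, x$to, collapse = " "), "\n")
  invisible(x)
}

#' Predict the categorical activity of an interface mutant
#'
#' Applies the design's substitutions to the native cross-interface pairs
#' and reads the outcome from the charge categories, in this precedence:
#' any pair turned repulsive -> "loss"; else any formerly
#' neutral/polar pair turned attractive -> "enhanced"; else a formerly
#' attractive pair preserved as attractive with swapped signs -> "rescue";
#' else "ambiguous". A design with no substitutions is the wild type,
#' "active". A substitution at a residue that appears in no native pair
#' triggers a warning and an "ambiguous" prediction.
#'
#' @param design a [mutant_design()] (or strings coercible to one).
#' @param pairs native pair table, default [rip2_native_pairs()].
#' @return list with `prediction` and `pairs` (per-pair evidence: native
#'   and mutant charges and categories).
#' @export
predict_activity <- function(design, pairs = rip2_native_pairs()) {
  if (!inherits(design, "mutant_design")) design <- mutant_design(design)
  if (nrow(design) == 0L)
    return(list(prediction = "active", pairs = pairs))
  sites <- c(pairs$res_i, pairs$res_j)
  orphan <- setdiff(design$site, sites)
  if (length(orphan)) {
    warning(sprintf("substitution at non-interface residue(s) %s; prediction is ambiguous",
                    paste(orphan, collapse = ", ")))
    return(list(prediction = "ambiguous", pairs = NULL))
  }
  mut_code <- function(res, wt) {
    k <- match(res, design$site)
    ifelse(is.na(k), wt, design$to[k])
  }
  affected <- pairs[pairs$res_i %in% design$site | pairs$res_j %in% design$site, ]
  ev <- do.call(rbind, lapply(seq_len(nrow(affected)), function(r) {
    p <- affected[r, ]
    qi0 <- residue_charge(p$code_i); qj0 <- residue_charge(p$code_j)
    ci <- mut_code(p$res_i, p$code_i); cj <- mut_code(p$res_j, p$code_j)
    qi1 <- residue_charge(ci); qj1 <- residue_charge(cj)
    both <- p$res_i %in% design$site && p$res_j %in% design$site
    data.frame(res_i = p$res_i, res_j = p$res_j,
               native = pair_category(qi0, qj0),
               mutant = pair_category(qi1, qj1),
               swapped = both && qi1 == qj0 && qj1 == qi0,
               stringsAsFactors = FALSE)
  }))
  prediction <-
    if (any(ev$mutant == "repulsive")) "loss"
    else if (any(ev$native != "attractive" & ev$mutant == "attractive")) "enhanced"
    else if (any(ev$native == "attractive" & ev$mutant == "attractive" &
                   ev$swapped)) "rescue"
    else "ambiguous"
  list(prediction = prediction, pairs = ev)
}

#' Surface-silencing mutation designs
#'
#' The designs used to disable self-oligomerisation on one axial face of
#' RIP2-CARD: bottom = \{R444E, E445R\}, top = \{N449A, K513E\}. Both
#' predict loss of self-assembly on their side. (The running text once
#' prints "N495A" for the top pair; no N495 exists in any published patch,
#' so N449A - as in the figure legend - is used.)
#'
#' @param side "top" or "bottom".
#' @return list with `side`, `design` (a [mutant_design()]) and
#'   `prediction`.
#' @export
silencing_mutations <- function(side = c("top", "bottom")) {
  side <- match.arg(side)
  design <- if (side == "bottom") mutant_design("R444E", "E445R")
            else mutant_design("N449A", "K513E")
  list(side = side, design = design,
       prediction = predict_activity(design)$prediction)
}
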
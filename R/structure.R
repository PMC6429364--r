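# Structure data model: an mt_structure is a tibble of atoms with one row per
# atom and columns
#   eleno, elety, element, is_heavy, x, y, z, chain, resno, resname,
#   segment, group, charge, radius
# `group` partitions atoms into "binder", "filament", "tail_A".."tail_D" or
# "" (ungrouped); `segment` carries finer annotation (H1..H6, LH1, FLAP, ...).

#' Create a structure from an atom table
#'
#' @param atoms data frame with at least `elety`, `x`, `y`, `z`, `chain`,
#'   `resno`, `resname`; missing optional columns (`eleno`, `element`,
#'   `segment`, `group`, `charge`, `radius`) are filled with defaults.
#' @return A tibble of class `mt_structure`.
#' @export
mt_structure <- function(atoms) {
  a <- as_tibble(atoms)
  need <- c("elety", "x", "y", "z", "chain", "resno", "resname")
  miss <- setdiff(need, names(a))
  if (length(miss) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  n <- nrow(a)
  if (!"eleno" %in% names(a)) a$eleno <- seq_len(n)
  if (!"element" %in% names(a)) a$element <- infer_element(a$elety)
  a$element[is.na(a$element)] <- infer_element(a$elety[is.na(a$element)])
  if (!"segment" %in% names(a)) a$segment <- rep("OTHER", n)
  a$segment[is.na(a$segment)] <- "OTHER"
  if (!"group" %in% names(a)) a$group <- rep("", n)
  a$group[is.na(a$group)] <- ""
  if (!"charge" %in% names(a)) a$charge <- rep(0, n)
  a$charge[is.na(a$charge)] <- 0
  if (!"radius" %in% names(a)) a$radius <- element_radius(a$element)
  a$radius[is.na(a$radius)] <- element_radius(a$element[is.na(a$radius)])
  a$is_heavy <- a$element != "H"
  coords <- as.matrix(a[, c("x", "y", "z")])
  if (n > 0 && !all(is.finite(coords))) abort("non-finite atom coordinates")
  if (any(a$is_heavy & !(a$radius > 0))) abort("heavy atoms must have radius > 0")
  a <- a[, c("eleno", "elety", "element", "is_heavy", "x", "y", "z",
             "chain", "resno", "resname", "segment", "group", "charge", "radius")]
  class(a) <- c("mt_structure", class(tibble()))
  a
}

#' @export
print.mt_structure <- function(x, ...) {
  cat(sprintf("<mt_structure> %d atoms, %d residues, net charge %+.1f e\n",
              nrow(x), n_residues(x), sum(x$charge)))
  NextMethod()
}

#' Number of distinct residues in a structure
#' @param s an `mt_structure`.
#' @return Integer count of unique (chain, resno) pairs.
#' @export
n_residues <- function(s) {
  if (nrow(s) == 0) return(0L)
  length(unique(paste(s$chain, s$resno)))
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s an `mt_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  unname(as.matrix(s[, c("x", "y", "z")]))
}

#' Replace coordinates of a structure
#' @param s an `mt_structure`.
#' @param xyz n x 3 matrix.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

#' Row indices of a named atom group
#' @param s an `mt_structure`.
#' @param group group label, e.g. `"binder"`, `"filament"`, `"tail_B"`.
#' @return Integer vector of row indices.
#' @export
group_idx <- function(s, group) {
  which(s$group %in% group)
}

#' Net formal charge of a structure
#' @param s an `mt_structure`.
#' @return Sum of per-atom charges in elementary units.
#' @export
net_charge <- function(s) sum(s$charge)

infer_element <- function(elety) {
  # strip leading digits (e.g. "1HB"), take leading alpha run, then match
  # two-letter elements first, else first letter
  core <- toupper(sub("^[0-9]*", "", trimws(elety)))
  first2 <- substr(core, 1, 2)
  first1 <- substr(core, 1, 1)
  ifelse(first2 %in% c("CL", "BR", "FE", "ZN", "MG", "NA") &
           !grepl("^C[ABGDEZ]", core) & !grepl("^N[ABGDEZH]", core),
         first2, first1)
}

element_radius <- function(element) {
  r <- ELEMENT_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_RADIUS
  unname(r)
}

# ---------------------------------------------------------------------------
# Rigid transforms

#' Apply a rigid transform to a structure
#'
#' Maps every coordinate x to `R x + t`. All non-coordinate fields are
#' unchanged.
#'
#' @param s an `mt_structure`.
#' @param rot 3x3 proper rotation matrix (orthonormal, det = +1 within 1e-6).
#' @param trans length-3 translation vector.
#' @return Transformed structure.
#' @export
apply_transform <- function(s, rot = diag(3), trans = c(0, 0, 0)) {
  check_rotation(rot)
  stopifnot(length(trans) == 3)
  xyz <- coords(s)
  if (nrow(xyz) > 0) {
    xyz <- xyz %*% t(rot)
    xyz <- sweep(xyz, 2, trans, "+")
  }
  set_coords(s, xyz)
}

check_rotation <- function(rot, tol = 1e-6) {
  if (!is.matrix(rot) || any(dim(rot) != c(3, 3))) {
    abort("rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(rot) - diag(3))) > tol || abs(det(rot) - 1) > tol) {
    abort("matrix is not a proper rotation (orthonormal with det = +1)")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Offset protocol

#' Perpendicular offset protocol
#'
#' The displacement axis (unit vector perpendicular to the filament long
#' axis) and the set of offset distances at which the binder is placed.
#'
#' @param axis length-3 vector; normalised internally, must be non-zero.
#' @param distances offsets in Angstrom; non-negative, strictly increasing.
#' @return A list of class `offset_protocol`.
#' @export
offset_protocol <- function(axis = c(0, 0, 1),
                            distances = c(0, 5, 15, 25, 35, 45, 55)) {
  stopifnot(length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort("offset axis must be non-zero")
  axis <- axis / nrm
  if (any(distances < 0)) abort("offset distances must be non-negative")
  if (is.unsorted(distances, strictly = TRUE)) {
    abort("offset distances must be strictly increasing")
  }
  structure(list(axis = axis, distances = distances), class = "offset_protocol")
}

#' Displace the binder group along the offset axis
#'
#' Translates only the atoms of the `"binder"` group by `d` Angstrom along
#' the protocol axis; filament and tail atoms are untouched.
#'
#' @param s an `mt_structure` with a non-empty `"binder"` group.
#' @param d offset in Angstrom (negative values undo a previous offset).
#' @param protocol an [offset_protocol()].
#' @return The offset structure.
#' @export
offset_binder <- function(s, d, protocol = offset_protocol()) {
  idx <- group_idx(s, "binder")
  if (length(idx) == 0) abort("structure has no 'binder' group")
  shift <- d * protocol$axis
  s$x[idx] <- s$x[idx] + shift[1]
  s$y[idx] <- s$y[idx] + shift[2]
  s$z[idx] <- s$z[idx] + shift[3]
  s
}

# ---------------------------------------------------------------------------
# Clash removal

#' Remove binder-filament clashes by translation along the offset axis
#'
#' Iteratively translates the binder group along +axis in 0.5 Angstrom steps
#' until no binder-filament heavy-atom pair lies below `cutoff`. Filament and
#' tail atoms are never moved.
#'
#' @param s an `mt_structure` with `"binder"` and `"filament"` groups.
#' @param cutoff clash distance in Angstrom (> 0).
#' @param protocol an [offset_protocol()] supplying the axis.
#' @param step translation increment in Angstrom.
#' @return The de-clashed structure, with attributes `clash_report` (tibble of
#'   initial clashing pairs with distances) and `displacement` (total Angstrom
#'   moved); retrieve with [clash_report()].
#' @export
remove_clashes <- function(s, cutoff = 2.0, protocol = offset_protocol(),
                           step = 0.5) {
  stopifnot(cutoff > 0, step > 0)
  ib <- intersect(group_idx(s, "binder"), which(s$is_heavy))
  if_ <- intersect(group_idx(s, "filament"), which(s$is_heavy))
  if (length(ib) == 0) abort("structure has no 'binder' group")
  report <- clash_pairs(coords(s), ib, if_, cutoff)
  displacement <- 0
  while (nrow(clash_pairs(coords(s), ib, if_, cutoff)) > 0) {
    s <- offset_binder(s, step, protocol)
    displacement <- displacement + step
    if (displacement > 1e4) abort("clash removal failed to converge")
  }
  attr(s, "clash_report") <- report
  attr(s, "displacement") <- displacement
  s
}

#' Clash report from [remove_clashes()]
#' @param s structure returned by [remove_clashes()].
#' @return A list with `pairs` (tibble of initial clashing atom pairs) and
#'   `displacement` (total Angstrom the binder was moved).
#' @export
clash_report <- function(s) {
  list(pairs = attr(s, "clash_report"),
       displacement = attr(s, "displacement") %||% 0)
}

clash_pairs <- function(xyz, ia, ib, cutoff) {
  if (length(ia) == 0 || length(ib) == 0) {
    return(tibble(i = integer(), j = integer(), distance = numeric()))
  }
  d2 <- pair_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  tibble(i = ia[hit[, 1]], j = ib[hit[, 2]],
         distance = sqrt(d2[hit]))
}

# squared distances between two coordinate sets (na x nb matrix)
pair_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

# ---------------------------------------------------------------------------
# Ionization

#' Fixed-pKa ionization rules
#'
#' Model pKa values for titratable side chains. At pH 7 these reproduce the
#' standard picture for this system: Asp/Glu fully deprotonated (-1),
#' Lys/Arg fully protonated (+1), His neutral.
#'
#' @param pH solution pH.
#' @param model_pKa named vector of side-chain pKa values.
#' @return A list of class `ionization_rules`.
#' @export
ionization_rules <- function(pH = 7,
                             model_pKa = c(ASP = 3.65, GLU = 4.25, HIS = 6.0,
                                           LYS = 10.53, ARG = 12.48)) {
  structure(list(pH = pH, model_pKa = model_pKa,
                 acids = c("ASP", "GLU"), bases = c("HIS", "LYS", "ARG")),
            class = "ionization_rules")
}

residue_formal_charge <- function(resname, rules) {
  ch <- numeric(length(resname))
  for (res in intersect(names(rules$model_pKa), unique(resname))) {
    sel <- resname == res
    if (res %in% rules$acids) {
      ch[sel] <- ifelse(rules$pH > rules$model_pKa[[res]], -1, 0)
    } else {
      ch[sel] <- ifelse(rules$pH < rules$model_pKa[[res]], +1, 0)
    }
  }
  ch
}

#' Assign side-chain formal charges by fixed-pKa rules
#'
#' Sets the `charge` column: each titratable residue receives an integer
#' formal charge (-1, 0 or +1) decided by comparing pH with its model pKa,
#' placed on the residue's charge-bearing side-chain atom (CG/CD/NZ/CZ/ND1
#' for all-atom structures, the `SC` pseudo-atom for built tails, the
#' residue's single bead otherwise). Termini are left uncharged unless
#' `charge_termini` is set (tails are internal fragments of tubulin).
#'
#' @param s an `mt_structure`.
#' @param rules an [ionization_rules()] object.
#' @param charge_termini if `TRUE`, adds +1 to the first atom and -1 to the
#'   last atom of each chain.
#' @return The structure with charges assigned; net charge equals
#'   `(#LYS + #ARG) - (#ASP + #GLU)` at pH 7 (plus termini if requested).
#' @export
assign_ionization <- function(s, rules = ionization_rules(),
                              charge_termini = FALSE) {
  s$charge <- 0
  if (nrow(s) == 0) return(s)
  res_key <- paste(s$chain, s$resno, s$resname)
  for (key in unique(res_key)) {
    rows <- which(res_key == key)
    resname <- s$resname[rows[1]]
    q <- residue_formal_charge(resname, rules)
    if (q == 0) next
    bearer <- rows[s$elety[rows] == "SC"]
    if (length(bearer) == 0 && resname %in% names(CHARGE_BEARER)) {
      bearer <- rows[s$elety[rows] == CHARGE_BEARER[[resname]]]
    }
    if (length(bearer) == 0) bearer <- rows[1]
    s$charge[bearer[1]] <- q
  }
  if (charge_termini) {
    for (ch in unique(s$chain)) {
      rows <- which(s$chain == ch)
      s$charge[rows[1]] <- s$charge[rows[1]] + 1
      s$charge[rows[length(rows)]] <- s$charge[rows[length(rows)]] - 1
    }
  }
  s
}

# ---------------------------------------------------------------------------
# Extended tail builder

#' Build an extended disordered tail from sequence
#'
#' Constructs an all-trans pseudo-chain: one CA bead per residue at 3.8
#' Angstrom spacing along `direction` starting from `anchor`, plus one `SC`
#' side-chain pseudo-atom (2.5 Angstrom off-axis, alternating sides) for each
#' titratable residue to carry its formal charge. This coarse representation
#' supports the downstream contact and electrostatic analyses; no attempt
#' is made at realistic backbone geometry.
#'
#' @param sequence one-letter amino-acid string (may be empty).
#' @param anchor length-3 start coordinate.
#' @param direction length-3 growth direction (normalised internally).
#' @param chain chain identifier for the built residues.
#' @param segment segment tag (e.g. `"TAIL_B"`).
#' @param group group label (e.g. `"tail_B"`).
#' @param start_resno residue number of the first residue.
#' @return An `mt_structure` with one residue per letter.
#' @export
build_extended_tail <- function(sequence, anchor = c(0, 0, 0),
                                direction = c(0, 0, 1), chain = "T",
                                segment = "OTHER", group = "",
                                start_resno = 1L) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0) {
    return(mt_structure(tibble(elety = character(), x = numeric(),
                               y = numeric(), z = numeric(),
                               chain = character(), resno = integer(),
                               resname = character())))
  }
  unknown <- setdiff(letters1, names(AA_THREE))
  if (length(unknown) > 0) {
    abort(paste0("unknown amino-acid letter(s): ", paste(unknown, collapse = ", ")))
  }
  dirn <- direction / sqrt(sum(direction^2))
  # any unit vector perpendicular to dirn, for side-chain placement
  ref <- if (abs(dirn[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * dirn) * dirn
  perp <- perp / sqrt(sum(perp^2))

  resnames <- AA_THREE[letters1]
  n <- length(letters1)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    ca <- anchor + (k - 1) * 3.8 * dirn
    atoms <- tibble(elety = "CA", element = "C",
                    x = ca[1], y = ca[2], z = ca[3],
                    chain = chain, resno = start_resno + k - 1L,
                    resname = resnames[[k]])
    if (resnames[[k]] %in% c("ASP", "GLU", "LYS", "ARG", "HIS")) {
      sc <- ca + 2.5 * perp * (-1)^k
      atoms <- bind_rows(atoms, tibble(
        elety = "SC", element = ifelse(resnames[[k]] %in% c("ASP", "GLU"), "O", "N"),
        x = sc[1], y = sc[2], z = sc[3],
        chain = chain, resno = start_resno + k - 1L, resname = resnames[[k]]))
    }
    rows[[k]] <- atoms
  }
  out <- bind_rows(rows)
  out$segment <- segment
  out$group <- group
  mt_structure(out)
}
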
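# Building blocks: precursor molecules (tri-topic aldehydes, di-topic primary
# amines), their filtering into a database, Dice similarity over Morgan
# fingerprints, similarity ranking, and the per-molecule descriptors tracked
# by the population analytics.

#' Classify the reactive-group topicity of a molecule
#'
#' Counts aldehyde groups (`[CX3H1](=O)` on carbon) and primary amines
#' (`[NX3;H2]` not adjacent to a carbonyl, so amides do not count, as an amide
#' nitrogen cannot undergo imine condensation).
#'
#' @param smiles A single SMILES string.
#' @return A list with `group` (one of `"aldehyde"`, `"primary_amine"`,
#'   `"none"`) and `count` (number of reactive groups). Molecules showing both
#'   group types, or neither, classify as `"none"`.
#' @export
classify_topicity <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  if (!smiles_parseable(smiles)) stop("unparseable SMILES: ", smiles)
  n_ald <- smarts_count(smiles, .SMARTS_ALDEHYDE)
  n_amn <- smarts_count(smiles, .SMARTS_PRIMARY_AMINE)
  if (n_ald > 0L && n_amn == 0L) {
    list(group = "aldehyde", count = n_ald)
  } else if (n_amn > 0L && n_ald == 0L) {
    list(group = "primary_amine", count = n_amn)
  } else {
    list(group = "none", count = 0L)
  }
}

#' Construct a building block
#'
#' @param smiles SMILES string (canonicalized on construction).
#' @param id Stable string key.
#' @param conformer Optional embedded conformer (see [embed_smiles()]).
#' @param fingerprint Optional precomputed fingerprint; computed when missing.
#' @return An object of class `building_block` with fields `id`, `smiles`,
#'   `role`, `topicity`, `fingerprint`, `conformer`, `molecular_weight`.
#' @export
building_block <- function(smiles, id, conformer = NULL, fingerprint = NULL) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", smiles)
  cls <- classify_topicity(can)
  role <- switch(cls$group, aldehyde = "trialdehyde",
                 primary_amine = "diamine", "none")
  if (is.null(fingerprint)) fingerprint <- morgan_fingerprint(can)[[1]]
  mw <- if (!is.null(conformer)) sum(atomic_mass(conformer$elements)) else NA_real_
  structure(
    list(id = as.character(id), smiles = can, role = role,
         topicity = cls$count, fingerprint = fingerprint,
         conformer = conformer, molecular_weight = mw),
    class = "building_block"
  )
}

# Synthetic stand-in used by abstract fitness landscapes: no molecule behind
# it, just an id, a role and a fingerprint so similarity-based operators work.
synthetic_building_block <- function(id, role, fingerprint) {
  structure(
    list(id = as.character(id), smiles = NA_character_, role = role,
         topicity = if (role == "trialdehyde") 3L else 2L,
         fingerprint = fingerprint, conformer = NULL,
         molecular_weight = NA_real_),
    class = "building_block"
  )
}

#' @export
print.building_block <- function(x, ...) {
  cat("<building_block>", x$id, " ", x$role,
      " topicity=", x$topicity, "\n  ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Filter a raw SMILES list into a building-block database
#'
#' Applies the library curation rules: molecules must parse, carry no formal
#' charges, contain no metals, and classify as exactly tri-topic aldehydes or
#' di-topic primary amines. Duplicate canonical SMILES are collapsed. Retained
#' molecules get one embedded ETKDG conformer each.
#'
#' @param raw Character vector of SMILES.
#' @param ids Optional ids; generated (`tri-NNN` / `di-NNN`) when missing.
#' @param embed_seed Seed for conformer embedding.
#' @param embed Embed 3D conformers for retained members (default `TRUE`).
#' @param provenance Free-text label stored on the database.
#' @return A `bb_database`: members sorted by id, with a `removed` attribute
#'   (data frame of per-rule removal counts).
#' @export
filter_database <- function(raw, ids = NULL, embed_seed = 1L, embed = TRUE,
                            provenance = "") {
  stopifnot(is.character(raw))
  if (length(raw) == 0L) stop("non-empty SMILES list required")
  if (!is.null(ids)) stopifnot(length(ids) == length(raw))
  removed <- c(unparseable = 0L, charged = 0L, metal = 0L,
               wrong_topicity = 0L, duplicate = 0L, embed_failed = 0L)

  df <- data.frame(can = canonical_smiles(raw),
                   id = if (is.null(ids)) NA_character_ else as.character(ids),
                   stringsAsFactors = FALSE)
  removed[["unparseable"]] <- sum(is.na(df$can))
  df <- df[!is.na(df$can), , drop = FALSE]

  dup <- duplicated(df$can)
  removed[["duplicate"]] <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  if (nrow(df)) {
    chg <- is_charged(df$can)
    removed[["charged"]] <- sum(chg, na.rm = TRUE)
    df <- df[!chg %in% TRUE, , drop = FALSE]
  }
  if (nrow(df)) {
    met <- contains_metal(df$can)
    removed[["metal"]] <- sum(met, na.rm = TRUE)
    df <- df[!met %in% TRUE, , drop = FALSE]
  }

  members <- list()
  if (nrow(df)) {
    cls <- lapply(df$can, classify_topicity)
    ok <- vapply(cls, function(x) {
      (x$group == "aldehyde" && x$count == 3L) ||
        (x$group == "primary_amine" && x$count == 2L)
    }, logical(1))
    removed[["wrong_topicity"]] <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    cls <- cls[ok]
  }

  if (nrow(df)) {
    is_tri <- vapply(cls, function(x) x$group == "aldehyde", logical(1))
    auto <- character(nrow(df))
    auto[is_tri] <- sprintf("tri-%03d", seq_len(sum(is_tri)))
    auto[!is_tri] <- sprintf("di-%03d", seq_len(sum(!is_tri)))
    df$id <- ifelse(is.na(df$id), auto, df$id)
    if (anyDuplicated(df$id)) stop("duplicate ids after filtering")
    confs <- if (embed) embed_smiles(df$can, seed = embed_seed, ids = df$id)
             else stats::setNames(vector("list", nrow(df)), df$id)
    for (k in seq_len(nrow(df))) {
      conf <- confs[[df$id[k]]]
      if (embed && is.null(conf)) {
        removed[["embed_failed"]] <- removed[["embed_failed"]] + 1L
        next
      }
      members[[df$id[k]]] <- building_block(df$can[k], df$id[k],
                                            conformer = conf)
    }
  }

  if (length(members) == 0L) {
    warning("filter produced an empty database")
  } else {
    members <- members[order(names(members))]
  }
  structure(
    list(members = members, provenance = provenance),
    removed = data.frame(rule = names(removed), n = unname(removed)),
    class = "bb_database"
  )
}

#' Assemble a database directly from curated building blocks
#'
#' @param members A list of `building_block` objects with unique ids.
#' @param provenance Free-text label.
#' @return A `bb_database`.
#' @export
bb_database <- function(members, provenance = "") {
  ids <- vapply(members, `[[`, character(1), "id")
  stopifnot(!anyDuplicated(ids))
  names(members) <- ids
  members <- members[order(ids)]
  structure(list(members = members, provenance = provenance),
            class = "bb_database")
}

#' @export
print.bb_database <- function(x, ...) {
  roles <- vapply(x$members, `[[`, character(1), "role")
  cat("<bb_database> ", length(x$members), " members (",
      sum(roles == "trialdehyde"), " trialdehydes, ",
      sum(roles == "diamine"), " diamines)\n", sep = "")
  invisible(x)
}

#' @export
length.bb_database <- function(x) length(x$members)

db_ids <- function(db, role = NULL) {
  ids <- names(db$members)
  if (!is.null(role)) {
    roles <- vapply(db$members, `[[`, character(1), "role")
    ids <- ids[roles == role]
  }
  ids
}

db_get <- function(db, id) {
  bb <- db$members[[id]]
  if (is.null(bb)) stop("no building block with id ", id)
  bb
}

#' Dice similarity between two building blocks
#'
#' `2|A & B| / (|A| + |B|)` over fingerprint on-bits. Two all-zero
#' fingerprints count as identical (similarity 1).
#'
#' @param a,b `building_block`s with fingerprints of identical parameters.
#' @return Similarity in \[0, 1\].
#' @export
dice_similarity <- function(a, b) {
  fa <- if (inherits(a, "building_block")) a$fingerprint else a
  fb <- if (inherits(b, "building_block")) b$fingerprint else b
  if (length(fa) != length(fb) ||
      !identical(attr(fa, "radius"), attr(fb, "radius"))) {
    stop("fingerprint parameters differ between molecules")
  }
  na <- sum(fa != 0); nb <- sum(fb != 0)
  if (na + nb == 0L) return(1)
  2 * sum(fa != 0 & fb != 0) / (na + nb)
}

#' Rank database members by similarity to a target
#'
#' Returns the n-th most Dice-similar member of the target's role, excluding
#' the target itself (by canonical SMILES and id). Ties break by ascending id
#' so ranked queries are reproducible.
#'
#' @param target A `building_block`.
#' @param db A `bb_database`.
#' @param n Rank to return (1 = most similar).
#' @return The ranked `building_block`.
#' @export
similarity_rank <- function(target, db, n) {
  stopifnot(n >= 1L)
  ids <- db_ids(db, role = target$role)
  ids <- ids[vapply(ids, function(i) {
    bb <- db$members[[i]]
    bb$id != target$id &&
      !(!is.na(bb$smiles) && !is.na(target$smiles) && bb$smiles == target$smiles)
  }, logical(1))]
  if (n > length(ids)) {
    stop("rank ", n, " exceeds the ", length(ids),
         " available members of role ", target$role)
  }
  sims <- vapply(ids, function(i) dice_similarity(target, db$members[[i]]),
                 numeric(1))
  ord <- order(-sims, ids)
  db$members[[ids[ord[n]]]]
}

# Anchor atoms of the reactive groups on the explicit-H conformer graph:
# carbonyl carbon (C with a double-bonded O and one H) for aldehydes, amine
# nitrogen (N with exactly two H neighbours, none of them via a carbonyl C)
# for diamines. Returns atom indices into the conformer.
find_anchor_atoms <- function(conformer, role) {
  el <- conformer$elements
  bonds <- conformer$bonds
  nb <- function(i) {
    rows <- bonds[, 1] == i | bonds[, 2] == i
    cbind(other = ifelse(bonds[rows, 1] == i, bonds[rows, 2], bonds[rows, 1]),
          order = bonds[rows, 3])
  }
  if (role == "trialdehyde") {
    cand <- which(el == "C")
    keep <- vapply(cand, function(i) {
      nbs <- nb(i)
      has_dbo <- any(el[nbs[, 1]] == "O" & nbs[, 2] == 2)
      n_h <- sum(el[nbs[, 1]] == "H")
      has_dbo && n_h == 1L
    }, logical(1))
    cand[keep]
  } else if (role == "diamine") {
    cand <- which(el == "N")
    keep <- vapply(cand, function(i) {
      nbs <- nb(i)
      n_h <- sum(el[nbs[, 1]] == "H")
      heavy <- nbs[el[nbs[, 1]] != "H", 1]
      amide <- any(vapply(heavy, function(c_at) {
        if (el[c_at] != "C") return(FALSE)
        cn <- nb(c_at)
        any(el[cn[, 1]] == "O" & cn[, 2] == 2)
      }, logical(1)))
      n_h == 2L && !amide
    }, logical(1))
    cand[keep]
  } else {
    stop("no anchor definition for role ", role)
  }
}

#' Building-block descriptors
#'
#' Percentage of rotatable and double bonds (over all bonds of the heavy-atom
#' connection table) and the mean pairwise distance between reactive-group
#' anchor atoms (amine N for diamines, carbonyl C for trialdehydes) in the
#' embedded conformer.
#'
#' @param bb A `building_block` with an embedded conformer.
#' @return A list with `pct_rotatable`, `pct_double` (both in \[0, 100\]) and
#'   `end_group_distance` (Angstrom).
#' @export
bb_descriptors <- function(bb) {
  stopifnot(inherits(bb, "building_block"))
  if (is.null(bb$conformer)) stop("building block ", bb$id, " has no conformer")
  bs <- bond_stats(bb$smiles)[[1]]
  anchors <- find_anchor_atoms(bb$conformer, bb$role)
  if (length(anchors) < 2L) stop("fewer than two anchor atoms found for ", bb$id)
  pairs <- utils::combn(anchors, 2)
  d <- apply(pairs, 2, function(p) {
    .dist3(bb$conformer$coords[p[1], ], bb$conformer$coords[p[2], ])
  })
  list(
    pct_rotatable = 100 * bs$n_rotatable / bs$n_bonds,
    pct_double = 100 * bs$n_double / bs$n_bonds,
    end_group_distance = mean(d)
  )
}

#' Read a SMILES list file
#'
#' One molecule per line, optionally `SMILES<TAB>id`.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `id` (`NA` when absent).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a database as a SMILES + id TSV
#'
#' @param db A `bb_database`.
#' @param path Output file.
#' @export
write_bb_database <- function(db, path) {
  lines <- vapply(db$members, function(bb) paste(bb$smiles, bb$id, sep = "\t"),
                  character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write the filter removal report as CSV
#'
#' @param db A `bb_database` produced by [filter_database()].
#' @param path Output file.
#' @export
write_filter_report <- function(db, path) {
  rep <- attr(db, "removed")
  if (is.null(rep)) stop("database carries no filter report")
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
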
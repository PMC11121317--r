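# Structure ingestion: PDB parsing into a residue-level record with Cmu
# pseudoatoms, interface identification, curation rules and redundancy removal.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

.is_hydrogen <- function(elety) grepl("^[0-9]*H", elety)

#' Parse an antibody-antigen complex from a PDB file
#'
#' Reads ATOM records, resolves alternate locations (highest occupancy wins,
#' ties go to altloc "A"), drops hydrogens, and computes the Cmu pseudoatom of
#' every residue: the arithmetic mean of its resolved heavy side-chain atoms,
#' falling back to the C-alpha coordinate for glycine and for residues with no
#' resolved side-chain heavy atom.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param chains Named list assigning roles: `heavy` and `light` are single
#'   chain identifiers, `antigen` one or more chain identifiers.
#' @param id Complex identifier; defaults to the file name.
#' @param cdr Optional character vector of CDR residue identifiers in
#'   `"<chain>:<resno><insert>"` form (e.g. `"H:100A"`), used to anchor the
#'   40-Angstrom interface filter in [find_interface()].
#' @return An object of class `abag_complex`: a list with `id`, a `residues`
#'   tibble (chain, resno, insert, res_id, aa, role, Cmu coordinates, side-atom
#'   count), an `atoms` tibble of heavy atoms, `cdr`, and `n_unk`, the number
#'   of UNK residues encountered (reported, never silently dropped).
#' @export
parse_complex <- function(pdb, chains, id = NULL) {
  stopifnot(is.list(chains))
  if (is.null(chains$heavy) || is.null(chains$light) || is.null(chains$antigen) ||
      length(chains$heavy) != 1 || length(chains$light) != 1 ||
      length(chains$antigen) < 1) {
    abort("`chains` must assign exactly one heavy, one light and >=1 antigen chain")
  }
  lines_mode <- length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])
  if (lines_mode) {
    txt <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(txt, path)
    if (is.null(id)) id <- "complex"
  } else {
    path <- pdb
    txt <- readLines(path, warn = FALSE)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  }
  .validate_atom_records(txt)

  pdbobj <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdbobj$atom)
  at <- at[at$type == "ATOM", ]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- at[!.is_hydrogen(at$elety), ]

  # altloc resolution: highest occupancy, ties prefer altloc "A" (then order)
  at$o[is.na(at$o)] <- 1
  at <- at %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) %>%
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()

  roles <- c(
    setNames("heavy", chains$heavy),
    setNames("light", chains$light),
    setNames(rep("antigen", length(chains$antigen)), chains$antigen)
  )
  missing_ch <- setdiff(names(roles), unique(at$chain))
  if (length(missing_ch)) {
    abort(paste0("declared chain(s) not found in structure: ",
                 paste(missing_ch, collapse = ", ")))
  }
  at <- at[at$chain %in% names(roles), ]
  at$role <- unname(roles[at$chain])
  at$res_id <- paste0(at$chain, ":", at$resno, at$insert)
  at$is_side <- !(at$elety %in% .BACKBONE)

  res <- at %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$res_id,
             .data$resid, .data$role) %>%
    summarise(
      n_side = sum(.data$is_side),
      cmu_x = if (sum(.data$is_side) > 0) mean(.data$x[.data$is_side])
              else if (any(.data$elety == "CA")) .data$x[.data$elety == "CA"][1]
              else mean(.data$x),
      cmu_y = if (sum(.data$is_side) > 0) mean(.data$y[.data$is_side])
              else if (any(.data$elety == "CA")) .data$y[.data$elety == "CA"][1]
              else mean(.data$y),
      cmu_z = if (sum(.data$is_side) > 0) mean(.data$z[.data$is_side])
              else if (any(.data$elety == "CA")) .data$z[.data$elety == "CA"][1]
              else mean(.data$z),
      .groups = "drop"
    ) %>%
    mutate(aa = suppressWarnings(bio3d::aa321(.data$resid))) %>%
    arrange(.data$chain, .data$resno, .data$insert)
  res$aa[res$resid == "UNK" | is.na(res$aa)] <- "X"
  n_unk <- sum(res$resid == "UNK")
  if (n_unk > 0) {
    warn(paste0(id, ": ", n_unk, " UNK residue(s) present"))
  }

  for (role in c("heavy", "light")) {
    if (!any(res$role == role)) {
      abort(paste0("chain for role '", role, "' has no protein residues"))
    }
  }

  structure(
    list(
      id = id,
      residues = select(res, "chain", "resno", "insert", "res_id", "resid",
                        "aa", "role", "n_side", "cmu_x", "cmu_y", "cmu_z"),
      atoms = select(at, "chain", "resno", "insert", "res_id", "elety",
                     "role", "is_side", "x", "y", "z"),
      cdr = NULL,
      n_unk = n_unk
    ),
    class = "abag_complex"
  )
}

# Pre-validate fixed-column numeric fields of ATOM/HETATM records so a broken
# record is reported with its line number (bio3d would fail opaquely).
.validate_atom_records <- function(txt) {
  rec <- grepl("^(ATOM |HETATM)", txt)
  for (i in which(rec)) {
    ln <- txt[i]
    if (nchar(ln) < 54) {
      abort(paste0("unparseable ATOM record at line ", i, ": too short"))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz)) {
      abort(paste0("unparseable ATOM record at line ", i,
                   ": non-numeric coordinate field"))
    }
  }
  invisible(TRUE)
}

#' @export
print.abag_complex <- function(x, ...) {
  cat("<abag_complex> ", x$id, "\n", sep = "")
  tb <- table(x$residues$role)
  cat("  residues:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Set CDR annotation on a complex
#'
#' @param x An `abag_complex`.
#' @param res_ids Character vector of residue identifiers (`"H:100A"` form).
#' @return The complex with CDR annotation attached.
#' @export
set_cdr <- function(x, res_ids) {
  stopifnot(inherits(x, "abag_complex"))
  x$cdr <- res_ids
  x
}

.cmu_matrix <- function(res) {
  m <- as.matrix(res[, c("cmu_x", "cmu_y", "cmu_z")])
  rownames(m) <- res$res_id
  m
}

#' Identify paratope and epitope residues
#'
#' A residue of the antibody (antigen) belongs to the paratope (epitope) iff
#' the distance between its Cmu pseudoatom and the Cmu of any partner residue
#' is at most `cutoff`. Members whose Cmu lies farther than `cdr_radius` from
#' the geometric centre of the CDRs are then removed; without CDR annotation
#' the centre is the centroid of all antibody interface residues.
#'
#' @param x An `abag_complex`.
#' @param cutoff Contact cutoff between Cmu pseudoatoms, in Angstrom.
#' @param cdr_radius Maximum distance from the CDR centre, in Angstrom.
#' @return A list with elements `paratope` and `epitope`, each an
#'   `interface_patch`: a tibble of member residues carrying attributes
#'   `side`, `partner_centroid`, `cdr_center`, `atoms` (per-atom detail of the
#'   members) and `complex_id`.
#' @export
find_interface <- function(x, cutoff = 6, cdr_radius = 40) {
  stopifnot(inherits(x, "abag_complex"), cutoff > 0)
  res <- x$residues
  ab <- res[res$role %in% c("heavy", "light"), ]
  ag <- res[res$role == "antigen", ]
  mab <- .cmu_matrix(ab)
  mag <- .cmu_matrix(ag)
  d2 <- outer(rowSums(mab^2), rowSums(mag^2), "+") - 2 * (mab %*% t(mag))
  d2[d2 < 0] <- 0
  hit <- sqrt(d2) <= cutoff
  para <- ab[rowSums(hit) > 0, ]
  epi <- ag[colSums(hit) > 0, ]
  if (nrow(para) == 0 || nrow(epi) == 0) {
    abort(paste0(x$id, ": no interface under the ", cutoff, " A cutoff"))
  }

  anchor <- para
  if (!is.null(x$cdr)) {
    in_cdr <- para$res_id %in% x$cdr
    if (any(in_cdr)) anchor <- para[in_cdr, ]
  }
  cdr_center <- colMeans(.cmu_matrix(anchor))

  keep_near <- function(df) {
    m <- .cmu_matrix(df)
    d <- sqrt(rowSums(sweep(m, 2, cdr_center)^2))
    df[d <= cdr_radius, ]
  }
  para <- keep_near(para)
  epi <- keep_near(epi)
  if (nrow(para) == 0 || nrow(epi) == 0) {
    abort(paste0(x$id, ": no interface within ", cdr_radius,
                 " A of the CDR centre"))
  }

  mk <- function(df, side, partner) {
    structure(
      df,
      side = side,
      partner_centroid = colMeans(.cmu_matrix(partner)),
      cdr_center = cdr_center,
      atoms = x$atoms[x$atoms$res_id %in% df$res_id, ],
      complex_id = x$id,
      class = c("interface_patch", class(tibble()))
    )
  }
  list(paratope = mk(para, "paratope", epi),
       epitope = mk(epi, "epitope", para))
}

#' Apply the dataset curation rules
#'
#' Applies, in order: protein antigen of at least 50 residues; heavy and light
#' chain both present (Fab/Fv requirement); at most 50 residues with missing
#' atomic coordinates; no UNK residues; an interface of at least 3 residues on
#' each side under the contact rule of [find_interface()]. Each discarded
#' complex cites exactly the first failing rule.
#'
#' @param records List of `abag_complex` objects.
#' @param metadata Optional tibble with columns `id`, `antigen_is_protein`
#'   (logical) and `n_missing_residues`; missing entries default to protein
#'   antigen and zero missing residues.
#' @param min_antigen_residues,max_missing,min_interface Rule thresholds.
#' @return A `curation_report` tibble: `id`, `status` (`"kept"`/`"discarded"`),
#'   `rule` (`NA` for kept complexes).
#' @export
curate_complexes <- function(records, metadata = NULL,
                             min_antigen_residues = 50,
                             max_missing = 50,
                             min_interface = 3) {
  meta_of <- function(id, col, default) {
    if (is.null(metadata) || !col %in% names(metadata)) return(default)
    i <- match(id, metadata$id)
    if (is.na(i) || is.na(metadata[[col]][i])) default else metadata[[col]][i]
  }
  rows <- purrr::map(records, function(rec) {
    res <- rec$residues
    n_ag <- sum(res$role == "antigen")
    rule <- NA_character_
    if (!isTRUE(meta_of(rec$id, "antigen_is_protein", TRUE)) ||
        n_ag < min_antigen_residues) {
      rule <- "antigen_size"
    } else if (!any(res$role == "heavy") || !any(res$role == "light")) {
      rule <- "fab_fv"
    } else if (meta_of(rec$id, "n_missing_residues", 0L) > max_missing) {
      rule <- "missing_residues"
    } else if (rec$n_unk > 0) {
      rule <- "unk"
    } else {
      iface <- tryCatch(find_interface(rec), error = function(e) NULL)
      if (is.null(iface) ||
          nrow(iface$paratope) < min_interface ||
          nrow(iface$epitope) < min_interface) {
        rule <- "interface_size"
      }
    }
    tibble(id = rec$id,
           status = if (is.na(rule)) "kept" else "discarded",
           rule = rule)
  })
  structure(bind_rows(rows), class = c("curation_report", class(tibble())))
}

#' Write a curation report as TSV
#' @param report A `curation_report`.
#' @param path Output file.
#' @export
write_curation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenated CDR and antigen sequences of a complex
#'
#' The CDR sequence concatenates CDR-annotated antibody residues when an
#' annotation is attached (heavy chain first, author ordering within chains),
#' otherwise the antibody interface residues, which proxy the CDR loops at the
#' antigen interface. The antigen sequence concatenates all antigen chains.
#'
#' @param x An `abag_complex`.
#' @return A one-row tibble: `id`, `cdr_seq`, `ag_seq`.
#' @export
complex_sequences <- function(x) {
  res <- x$residues
  res <- res[order(match(res$role, c("heavy", "light", "antigen")),
                   res$chain, res$resno, res$insert), ]
  ab <- res[res$role != "antigen", ]
  if (!is.null(x$cdr)) {
    cdr_res <- ab[ab$res_id %in% x$cdr, ]
  } else {
    iface <- find_interface(x)
    cdr_res <- ab[ab$res_id %in% iface$paratope$res_id, ]
  }
  tibble(
    id = x$id,
    cdr_seq = paste(cdr_res$aa, collapse = ""),
    ag_seq = paste(res$aa[res$role == "antigen"], collapse = "")
  )
}

# Global pairwise identity: matches / max(sequence lengths) on a global
# alignment scored match=1, mismatch=0, with a small gap-extension cost to
# keep alignments compact.
.seq_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  letters <- unique(c(strsplit(paste0(a, b), "")[[1]], "X"))
  sm <- diag(1, length(letters))
  dimnames(sm) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 0.1
  )
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

#' Remove redundant complexes by greedy sequence-identity clustering
#'
#' Complexes are grouped when both the concatenated-CDR identity exceeds
#' `cdr_identity` and the antigen identity exceeds `ag_identity`. Clustering is
#' greedy longest-antigen-first (ties broken by id), so the kept complex of
#' each group is the one with the longest antigen sequence.
#'
#' @param seqs Tibble with columns `id`, `cdr_seq`, `ag_seq`
#'   (see [complex_sequences()]).
#' @param cdr_identity,ag_identity Identity thresholds (exceeded strictly).
#' @return A tibble `id`, `cluster`, `kept` (logical); kept ids are the
#'   cluster representatives.
#' @export
dedup_complexes <- function(seqs, cdr_identity = 0.8, ag_identity = 0.9) {
  if (nrow(seqs) == 0) {
    return(tibble(id = character(), cluster = integer(), kept = logical()))
  }
  ord <- order(-nchar(seqs$ag_seq), seqs$id)
  s <- seqs[ord, ]
  n <- nrow(s)
  cluster <- rep(NA_integer_, n)
  ncl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    ncl <- ncl + 1L
    cluster[i] <- ncl
    if (i < n) for (j in (i + 1L):n) {
      if (!is.na(cluster[j])) next
      if (.seq_identity(s$cdr_seq[i], s$cdr_seq[j]) > cdr_identity &&
          .seq_identity(s$ag_seq[i], s$ag_seq[j]) > ag_identity) {
        cluster[j] <- ncl
      }
    }
  }
  out <- tibble(id = s$id, cluster = cluster,
                kept = !duplicated(cluster))
  out[match(seqs$id, out$id), ]
}

#' Apply a rigid motion to a complex
#'
#' Rotates and translates every atom and Cmu coordinate. Mainly used to test
#' and demonstrate the rigid-motion invariance of the imaging pipeline.
#'
#' @param x An `abag_complex`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric vector, Angstrom.
#' @return The transformed complex.
#' @export
transform_complex <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(x, "abag_complex"))
  rot <- function(m) sweep(m %*% t(rotation), 2, -translation)
  cm <- rot(as.matrix(x$residues[, c("cmu_x", "cmu_y", "cmu_z")]))
  x$residues$cmu_x <- cm[, 1]; x$residues$cmu_y <- cm[, 2]; x$residues$cmu_z <- cm[, 3]
  am <- rot(as.matrix(x$atoms[, c("x", "y", "z")]))
  x$atoms$x <- am[, 1]; x$atoms$y <- am[, 2]; x$atoms$z <- am[, 3]
  x
}

#' Read a chain-annotation manifest
#'
#' @param path TSV with columns `id`, `pdb_path`, `heavy_chain`, `light_chain`,
#'   `antigen_chains` (comma-separated), optional `cdr_residues`
#'   (comma-separated `"H:100A"` identifiers).
#' @return A list of `abag_complex` objects.
#' @export
read_complex_manifest <- function(path) {
  man <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  base <- dirname(path)
  purrr::pmap(man, function(id, pdb_path, heavy_chain, light_chain,
                            antigen_chains, ...) {
    extra <- list(...)
    p <- if (file.exists(pdb_path)) pdb_path else file.path(base, pdb_path)
    rec <- parse_complex(
      p,
      chains = list(heavy = heavy_chain, light = light_chain,
                    antigen = strsplit(antigen_chains, ",")[[1]]),
      id = id
    )
    if (!is.null(extra$cdr_residues) && !is.na(extra$cdr_residues) &&
        nzchar(extra$cdr_residues)) {
      rec <- set_cdr(rec, strsplit(extra$cdr_residues, ",")[[1]])
    }
    rec
  })
}
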
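# Synthetic fixtures with closed-form ground truth: planted-interface
# PAE matrices, toy two-chain structures with planted contact geometry,
# calibration point sets and binding-profile matrices. These stand in
# for GPU-scale structure prediction in tests and examples.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a planted-interface PAE fixture
#'
#' Builds a two-chain PAE matrix whose inter-chain blocks contain a
#' planted fraction of confident (low-PAE) entries on a uniform
#' background, with the symmetric cell positions planted in both
#' off-diagonal blocks. With `noise_sd = 0` the observed-contacts sum
#' has the closed form
#' `oc* = 2 * (k * (max_pae - pae_interface) + (la*lb - k) * (max_pae - pae_background))`
#' where `k = round(interface_fraction * la * lb)` planted cells per
#' block; the declared `ec*` and `score*` follow from the supplied
#' calibration. Gaussian noise, when requested, is clipped to
#' `[0, max_pae]` and voids the exact closed form (`exact = FALSE`).
#'
#' @param length_a,length_b Chain lengths in residues (chain A is bait,
#'   chain B prey).
#' @param max_pae Error ceiling (Angstrom).
#' @param interface_fraction Fraction of each inter-chain block planted
#'   at `pae_interface`.
#' @param pae_interface,pae_background Planted and background inter-chain
#'   PAE values; must satisfy
#'   `0 <= pae_interface <= pae_background <= max_pae`.
#' @param pae_intra Intra-chain PAE fill value (never enters the score).
#' @param noise_sd Gaussian noise SD added to every entry, then clipped.
#' @param seed Integer seed; fixtures are byte-reproducible per
#'   (params, seed).
#' @param bait_name,prey_name Protein names recorded on the prediction.
#' @param calibration `spry_calibration` used for the declared `ec*`.
#' @param threshold Cutoff used for the declared classification.
#' @param dir If non-`NULL`, the PAE JSON is written under
#'   `dir/<bait>__<prey>/pae_rank_0.json` in `dialect`.
#' @param dialect JSON dialect for the emitted file.
#' @return List: `prediction` ([complex_prediction()]), `oc_star`,
#'   `ec_star`, `score_star`, `high_confidence_star`, `exact`,
#'   `n_planted` (k), and `path` when written.
#' @export
make_pae_fixture <- function(length_a, length_b, max_pae = 31.75,
                             interface_fraction = 1, pae_interface = 2,
                             pae_background = 29, pae_intra = 2,
                             noise_sd = 0, seed = 1,
                             bait_name = "BAIT", prey_name = "PREY",
                             calibration = default_calibration(),
                             threshold = 2.5, dir = NULL,
                             dialect = c("af3_full_data", "af2_nested_array",
                                         "af2_pairwise_list")) {
  dialect <- match.arg(dialect)
  if (!(pae_interface >= 0 && pae_interface <= pae_background &&
          pae_background <= max_pae))
    stop_spry("Need 0 <= pae_interface <= pae_background <= max_pae.",
              "parameter_error")
  if (interface_fraction < 0 || interface_fraction > 1)
    stop_spry("`interface_fraction` must lie in [0, 1].", "parameter_error")
  la <- as.integer(length_a); lb <- as.integer(length_b)
  n <- la + lb
  k <- as.integer(round(interface_fraction * la * lb))

  mat <- with_seed(seed, {
    m <- matrix(pae_intra, n, n)
    ai <- seq_len(la); bi <- la + seq_len(lb)
    m[ai, bi] <- pae_background
    m[bi, ai] <- pae_background
    if (k > 0) {
      cells <- sample.int(la * lb, k)
      ri <- ((cells - 1L) %% la) + 1L
      ci <- ((cells - 1L) %/% la) + 1L
      m[cbind(ri, la + ci)] <- pae_interface
      m[cbind(la + ci, ri)] <- pae_interface
    }
    diag(m) <- 0
    if (noise_sd > 0) {
      m <- m + rnorm(n * n, sd = noise_sd)
      m <- pmin(pmax(m, 0), max_pae)
    }
    m
  })

  partition <- chain_partition(
    tibble(chain = c("A", "B"), length = c(la, lb)), bait = "A", prey = "B")
  pae <- pae_matrix(mat, max_pae = max_pae, source_dialect = "synthetic")

  oc_star <- 2 * (k * (max_pae - pae_interface) +
                    (la * lb - k) * (max_pae - pae_background))
  len <- switch(calibration$length_definition,
                combined = la + lb, prey_only = lb)
  ec_star <- expected_contacts(len, calibration)
  score_star <- oc_star / ec_star

  path <- NULL
  if (!is.null(dir)) {
    pair_dir <- file.path(dir, paste0(bait_name, "__", prey_name))
    dir.create(pair_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(pair_dir, "pae_rank_0.json")
    write_pae_json(pae, path, dialect = dialect, partition = partition)
    if (dialect != "af3_full_data")
      write_partition_tsv(partition, file.path(pair_dir, "partition.tsv"))
  }

  list(
    prediction = complex_prediction(
      paste0(bait_name, "__", prey_name), bait_name, prey_name,
      pae, partition),
    oc_star = oc_star, ec_star = ec_star, score_star = score_star,
    high_confidence_star = score_star > threshold,
    exact = noise_sd == 0, n_planted = k, path = path)
}

write_partition_tsv <- function(partition, path) {
  role <- ifelse(partition$chains$chain == partition$bait, "bait",
                 ifelse(partition$chains$chain == partition$prey, "prey", "other"))
  readr::write_tsv(tibble(chain = partition$chains$chain,
                          length = partition$chains$length, role = role), path)
  invisible(path)
}

read_partition_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chain = readr::col_character(), length = readr::col_integer(),
    role = readr::col_character()))
  chain_partition(tab[, c("chain", "length")],
                  bait = tab$chain[tab$role == "bait"][1L],
                  prey = tab$chain[tab$role == "prey"][1L])
}

# minimal residue atom sets for toy structures; side-chain atoms beyond
# these are irrelevant to the contact rules
BACKBONE_ATOMS <- c("N", "CA", "C", "O")
SIDECHAIN_ATOMS <- list(
  ALA = "CB", GLY = character(), ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"), LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"), ASN = c("CB", "CG", "OD1", "ND2"),
  SER = c("CB", "OG"), LEU = c("CB", "CG", "CD1", "CD2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

atom_element <- function(elety) substr(gsub("^[0-9]", "", elety), 1, 1)

#' Generate a toy two-chain structure with planted contacts
#'
#' Each requested contact is realized by placing the two named atoms
#' exactly `distance` apart along the y axis (coordinates kept to three
#' decimals, so emitted PDB/mmCIF files reproduce the distance to
#' 1e-6 Angstrom), with all other atoms of the residue pair offset at
#' least 6 Angstrom further so the planted atom pair is the true
#' residue-pair minimum and no unintended polar or salt-bridge pair
#' arises. Contact sites are spaced 100 Angstrom apart; decoy residues
#' sit far beyond the contact cutoff from the opposite chain. Residues
#' are glycine/alanine-style minimal builds: backbone plus only the
#' side-chain atoms the contact rules inspect.
#'
#' @param contacts Data frame with columns `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `distance` (Angstrom), and optionally `class` (the
#'   intended contact class, recorded in the declaration).
#' @param n_decoys_a,n_decoys_b Decoy residue counts appended to each
#'   chain (ALA).
#' @param seed Seed for decoy jitter.
#' @param dir If non-`NULL`, writes `<basename>.pdb` and
#'   `<basename>.cif` there.
#' @param basename File stem for emitted structures.
#' @return List: `model` (`structure_model`), `declared` (tibble with
#'   chain/residue indices, planted distance and intended class), and
#'   `pdb_path`/`cif_path` when written.
#' @export
make_structure_fixture <- function(contacts, n_decoys_a = 2, n_decoys_b = 2,
                                   seed = 1, dir = NULL, basename = "toy") {
  contacts <- as_tibble(contacts)
  need <- c("res_a", "atom_a", "res_b", "atom_b", "distance")
  if (!all(need %in% names(contacts)))
    stop_spry(paste("`contacts` needs columns", paste(need, collapse = ", ")),
              "format_error")
  if (!"class" %in% names(contacts)) contacts$class <- NA_character_
  nc <- nrow(contacts)

  build_residue <- function(chain, resno, resname, key_atom, key_xyz,
                            far_y_sign) {
    atoms <- unique(c(BACKBONE_ATOMS,
                      SIDECHAIN_ATOMS[[resname]] %||% character(), key_atom))
    if (!key_atom %in% atoms)
      stop_spry(sprintf("Atom %s not buildable for residue %s.",
                        key_atom, resname), "geometry_error")
    xyz <- t(vapply(seq_along(atoms), function(j)
      key_xyz + c(0.9 * j, far_y_sign * (6 + 1.3 * j), 0), numeric(3)))
    xyz[atoms == key_atom, ] <- key_xyz
    tibble(chain = chain, resno_auth = resno, resid = resname,
           elety = atoms, elesy = atom_element(atoms),
           x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
           z = round(xyz[, 3], 3))
  }

  rows <- vector("list", 2L * nc + 2L)
  declared <- vector("list", nc)
  for (i in seq_len(nc)) {
    x0 <- (i - 1) * 100
    d <- contacts$distance[i]
    if (d <= 0)
      stop_spry("Planted distances must be > 0.", "geometry_error")
    rows[[2 * i - 1]] <- build_residue("A", i, contacts$res_a[i],
                                       contacts$atom_a[i], c(x0, 0, 0), -1)
    rows[[2 * i]] <- build_residue("B", i, contacts$res_b[i],
                                   contacts$atom_b[i], c(x0, round(d, 3), 0), +1)
    declared[[i]] <- tibble(
      chain_a = "A", resno_a = i, resid_a = contacts$res_a[i],
      chain_b = "B", resno_b = i, resid_b = contacts$res_b[i],
      distance = round(d, 3), class = contacts$class[i])
  }
  decoys <- with_seed(seed, {
    mk <- function(chain, count, y_base) {
      if (count == 0L) return(NULL)
      bind_rows(lapply(seq_len(count), function(j) {
        x0 <- -300 - 60 * j + round(stats::runif(1, -5, 5), 3)
        build_residue(chain, nc + j, "ALA", "CB",
                      c(x0, y_base + round(stats::runif(1, -5, 5), 3), 0),
                      +1)
      }))
    }
    list(a = mk("A", n_decoys_a, 0), b = mk("B", n_decoys_b, 1000))
  })
  model <- structure_model(bind_rows(c(rows[seq_len(2 * nc)],
                                       list(decoys$a, decoys$b))) |>
                             arrange(.data$chain, .data$resno_auth))
  out <- list(model = model, declared = bind_rows(declared))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$pdb_path <- write_pdb(model, file.path(dir, paste0(basename, ".pdb")))
    out$cif_path <- write_cif(model, file.path(dir, paste0(basename, ".cif")))
  }
  out
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output path (`.pdb`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  name_field <- ifelse(nchar(model$elety) < 4L,
                       sprintf(" %-3s", model$elety),
                       sprintf("%-4s", model$elety))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)), name_field, model$resid, model$chain,
    model$resno_auth, model$x, model$y, model$z, 1.0, 0.0, model$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as mmCIF
#'
#' Emits a minimal `atom_site` loop with the canonical column order.
#'
#' @param model A `structure_model`.
#' @param path Output path (`.cif`).
#' @return `path`, invisibly.
#' @export
write_cif <- function(model, path) {
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_entity_id",
            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
            "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
            "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  ent <- match(model$chain, unique(model$chain))
  body <- sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(model)), model$elesy, model$elety, model$resid, model$chain,
    ent, model$resno_auth, model$x, model$y, model$z,
    model$resno_auth, model$resid, model$chain, model$elety)
  writeLines(c("data_synthetic_toy", "#", "loop_",
               paste0("_atom_site.", cols), body, "#"), path)
  invisible(path)
}

#' Generate calibration points from a stated linear model
#'
#' `oc_i = slope * length_i + intercept + eps_i`, with
#' `eps ~ Normal(0, noise_sd^2)` drawn deterministically per seed.
#'
#' @param slope,intercept Line coefficients.
#' @param lengths Numeric vector of protein lengths (>= 2 distinct).
#' @param noise_sd Gaussian noise SD (0 for exact points).
#' @param seed Integer seed.
#' @return Tibble with columns `length`, `oc`.
#' @export
make_calibration_fixture <- function(slope, intercept, lengths,
                                     noise_sd = 0, seed = 1) {
  if (length(unique(lengths)) < 2L)
    stop_spry("Need >= 2 distinct lengths.", "parameter_error")
  eps <- if (noise_sd > 0)
    with_seed(seed, rnorm(length(lengths), sd = noise_sd))
  else rep(0, length(lengths))
  tibble(length = as.numeric(lengths),
         oc = slope * lengths + intercept + eps)
}

#' Generate a synthetic binding-profile matrix
#'
#' Scores drawn from a log-normal background centered below 1 (the bulk
#' of real screen scores) with a planted fraction of high-confidence
#' entries pushed above the cutoff.
#'
#' @param n_prey,n_bait Matrix dimensions.
#' @param high_fraction Fraction of entries planted above `threshold`.
#' @param threshold Cutoff used for planting.
#' @param seed Integer seed.
#' @return A `binding_profile` matrix.
#' @export
make_profile_fixture <- function(n_prey = 20, n_bait = 12,
                                 high_fraction = 0.05, threshold = 2.5,
                                 seed = 1) {
  with_seed(seed, {
    m <- matrix(stats::rlnorm(n_prey * n_bait, meanlog = log(0.45),
                              sdlog = 0.55), n_prey, n_bait)
    n_high <- round(high_fraction * n_prey * n_bait)
    if (n_high > 0) {
      idx <- sample.int(n_prey * n_bait, n_high)
      m[idx] <- threshold + stats::rlnorm(n_high, meanlog = log(1), sdlog = 0.4)
    }
    dimnames(m) <- list(sprintf("PREY%02d", seq_len(n_prey)),
                        sprintf("BAIT%02d", seq_len(n_bait)))
    binding_profile(m)
  })
}

#' Generate a directory of screen fixtures
#'
#' Writes `n_pairs` planted-interface PAE fixtures (one pair directory
#' each) of which `n_strong` carry a confident interface scoring above
#' the cutoff, plus a `manifest.tsv` of every declared ground-truth
#' value.
#'
#' @param dir Output directory (created).
#' @param n_pairs,n_strong Pair counts.
#' @param seed Integer seed (per-pair seeds derive from it).
#' @param length_a,length_b Chain lengths shared by all pairs.
#' @param dialect PAE JSON dialect to emit.
#' @param calibration,threshold Scoring configuration used for declared
#'   values.
#' @return Tibble manifest (one row per pair, with declared oc/ec/score
#'   and classification).
#' @export
make_screen_fixture <- function(dir, n_pairs = 6, n_strong = 2, seed = 1,
                                length_a = 150, length_b = 150,
                                dialect = "af3_full_data",
                                calibration = default_calibration(),
                                threshold = 2.5) {
  stopifnot(n_strong <= n_pairs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_len(n_pairs), function(i) {
    strong <- i <= n_strong
    fx <- make_pae_fixture(
      length_a, length_b,
      interface_fraction = if (strong) 1 else 0,
      pae_interface = 2, pae_background = if (strong) 29 else 29.5,
      seed = seed * 1000L + i,
      bait_name = sprintf("SENSOR%02d", i),
      prey_name = sprintf("SPRY%02d", i),
      calibration = calibration, threshold = threshold,
      dir = dir, dialect = dialect)
    tibble(pair_id = fx$prediction$pair_id,
           bait = fx$prediction$bait_name, prey = fx$prediction$prey_name,
           oc_star = fx$oc_star, ec_star = fx$ec_star,
           score_star = fx$score_star,
           high_confidence_star = fx$high_confidence_star)
  }) |> bind_rows()
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
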
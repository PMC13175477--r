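# Residue-level interface characterization: contacts, contact classes,
# domain mapping.

SALT_ACID_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SALT_BASE_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

heavy_atoms <- function(model) {
  model[!(toupper(model$elesy) %in% "H"), , drop = FALSE]
}

#' Inter-chain residue contacts
#'
#' Finds every residue pair, one residue on each chain, whose minimum
#' heavy-atom (non-hydrogen) distance is at or below `cutoff`. The
#' recorded distance is that true minimum over atom pairs. 5 Angstrom
#' heavy-atom is the common structural-biology contact convention.
#'
#' @param model A `structure_model`.
#' @param chain_a,chain_b Chain identifiers (must differ).
#' @param cutoff Contact cutoff in Angstrom (`> 0`).
#' @return Tibble of class `contact_table` sorted by (`resno_a`,
#'   `resno_b`): columns `chain_a`, `resno_a`, `resid_a`, `chain_b`,
#'   `resno_b`, `resid_b`, `distance`, `contact_class` (initialized
#'   `NA`; see [classify_contacts()]).
#' @export
inter_chain_contacts <- function(model, chain_a, chain_b, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  if (identical(chain_a, chain_b))
    stop_spry("Contacts are inter-chain only: chains must differ.",
              "chain_error")
  for (ch in c(chain_a, chain_b))
    if (!ch %in% model$chain)
      stop_spry(sprintf("Chain '%s' absent from structure.", ch), "chain_error")
  a <- heavy_atoms(model[model$chain == chain_a, ])
  b <- heavy_atoms(model[model$chain == chain_b, ])
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  # all-against-all heavy-atom distances (toy/interface scale: fine dense)
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * tcrossprod(ax, bx)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  hit <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    out <- tibble(chain_a = character(), resno_a = integer(),
                  resid_a = character(), chain_b = character(),
                  resno_b = integer(), resid_b = character(),
                  distance = numeric(), contact_class = character())
    class(out) <- c("contact_table", class(out))
    return(out)
  }
  pairs <- tibble(
    resno_a = a$resno[hit[, 1L]], resid_a = a$resid[hit[, 1L]],
    resno_b = b$resno[hit[, 2L]], resid_b = b$resid[hit[, 2L]],
    distance = dmat[hit])
  out <- pairs |>
    group_by(.data$resno_a, .data$resid_a, .data$resno_b, .data$resid_b) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    mutate(chain_a = chain_a, chain_b = chain_b,
           contact_class = NA_character_) |>
    select("chain_a", "resno_a", "resid_a", "chain_b", "resno_b", "resid_b",
           "distance", "contact_class") |>
    arrange(.data$resno_a, .data$resno_b)
  class(out) <- c("contact_table", class(out))
  out
}

min_pair_distance <- function(at_a, at_b) {
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) return(Inf)
  ax <- as.matrix(at_a[, c("x", "y", "z")])
  bx <- as.matrix(at_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * tcrossprod(ax, bx)
  sqrt(max(0, min(d2)))
}

classify_one_contact <- function(res_a, res_b, salt_bridge_cutoff, polar_cutoff) {
  # salt bridge: Asp/Glu side-chain carboxylate O vs Lys/Arg side-chain N,
  # in either direction
  sb <- function(acid, base) {
    acid_at <- acid[acid$elety %in% (SALT_ACID_ATOMS[[acid$resid[1L]]] %||%
                                       character()), , drop = FALSE]
    base_at <- base[base$elety %in% (SALT_BASE_ATOMS[[base$resid[1L]]] %||%
                                       character()), , drop = FALSE]
    min_pair_distance(acid_at, base_at) <= salt_bridge_cutoff
  }
  if (sb(res_a, res_b) || sb(res_b, res_a)) return("salt_bridge")
  # polar: any donor/acceptor heavy-atom (N or O, side chain or backbone) pair
  pol_a <- res_a[toupper(res_a$elesy) %in% c("N", "O"), , drop = FALSE]
  pol_b <- res_b[toupper(res_b$elesy) %in% c("N", "O"), , drop = FALSE]
  if (min_pair_distance(pol_a, pol_b) <= polar_cutoff) return("polar")
  "generic"
}

#' Classify inter-chain contacts
#'
#' Fills the `contact_class` column: `salt_bridge` when a side-chain
#' carboxylate oxygen of Asp/Glu lies within `salt_bridge_cutoff` of a
#' side-chain nitrogen of Lys (NZ) or Arg (NE/NH1/NH2); otherwise
#' `polar` when some N/O heavy-atom pair (side chain or backbone, so a
#' Gln side chain against a backbone carbonyl counts) lies within
#' `polar_cutoff`; otherwise `generic`. The rule is symmetric in the
#' two residues. His is not treated as a salt-bridge partner, and the
#' free N-terminal amine is not a donor: only named side-chain atoms
#' qualify.
#'
#' @param contacts A `contact_table` from [inter_chain_contacts()].
#' @param model The `structure_model` the contacts derive from.
#' @param salt_bridge_cutoff N-O distance cutoff in Angstrom.
#' @param polar_cutoff Donor/acceptor distance cutoff in Angstrom.
#' @return The contact table with `contact_class` filled.
#' @export
classify_contacts <- function(contacts, model, salt_bridge_cutoff = 4.0,
                              polar_cutoff = 3.5) {
  if (nrow(contacts) == 0L) return(contacts)
  heavy <- heavy_atoms(model)
  cls <- vapply(seq_len(nrow(contacts)), function(i) {
    res_a <- heavy[heavy$chain == contacts$chain_a[i] &
                     heavy$resno == contacts$resno_a[i], , drop = FALSE]
    res_b <- heavy[heavy$chain == contacts$chain_b[i] &
                     heavy$resno == contacts$resno_b[i], , drop = FALSE]
    classify_one_contact(res_a, res_b, salt_bridge_cutoff, polar_cutoff)
  }, character(1))
  contacts$contact_class <- cls
  contacts
}

#' Read a domain-annotation table
#'
#' Four tab-separated columns: `protein`, `domain`, `start`, `end`
#' (1-based inclusive residue coordinates, matching the "404-630aa"
#' style of construct boundaries). Domains may nest or overlap.
#'
#' @param path Path to the TSV file.
#' @return Tibble with those four columns.
#' @export
read_domain_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(), domain = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer()))
  validate_domain_annotations(ann)
}

validate_domain_annotations <- function(ann) {
  ann <- as_tibble(ann)
  need <- c("protein", "domain", "start", "end")
  if (!all(need %in% names(ann)))
    stop_spry("Domain annotations need columns protein, domain, start, end.",
              "format_error")
  if (any(ann$start < 1L) || any(ann$end < ann$start))
    stop_spry("Domain annotations need 1 <= start <= end.", "format_error")
  ann
}

#' Fraction of a protein's contact residues inside a named domain
#'
#' Counts DISTINCT contact residues of the named protein's side of the
#' interface and returns the fraction lying within the `[start, end]`
#' (inclusive) span of the named domain.
#'
#' @param contacts A `contact_table`.
#' @param annotations Domain annotation tibble
#'   (see [read_domain_annotations()]).
#' @param protein Protein name to look up in `annotations`.
#' @param domain Domain name (e.g. `"SPRY"`).
#' @param chain Which chain of the contact table carries this protein.
#' @return Fraction in `[0, 1]`.
#' @export
domain_contact_fraction <- function(contacts, annotations, protein, domain,
                                    chain) {
  annotations <- validate_domain_annotations(annotations)
  side <- if (chain %in% contacts$chain_a) {
    unique(contacts$resno_a[contacts$chain_a == chain])
  } else {
    unique(contacts$resno_b[contacts$chain_b == chain])
  }
  if (length(side) == 0L)
    stop_spry(sprintf("No contact residues on chain '%s'.", chain),
              "undefined_fraction_error")
  spans <- annotations[annotations$protein == protein &
                         annotations$domain == domain, , drop = FALSE]
  if (nrow(spans) == 0L)
    stop_spry(sprintf("No '%s' annotation for protein '%s'.", domain, protein),
              "annotation_error")
  inside <- vapply(side, function(r)
    any(r >= spans$start & r <= spans$end), logical(1))
  mean(inside)
}

#' Summarize one predicted interface
#'
#' Contact counts by class plus the fraction of distinct prey-side
#' contact residues lying in the prey's SPRY domain (the screen's main
#' interface statistic), and per-domain contact-residue counts for every
#' annotated domain of the prey.
#'
#' @param pred A [complex_prediction()] carrying a structure.
#' @param annotations Domain annotation tibble; may be `NULL` to skip
#'   domain mapping.
#' @param cutoff,salt_bridge_cutoff,polar_cutoff Distance cutoffs in
#'   Angstrom (see [inter_chain_contacts()], [classify_contacts()]).
#' @param spry_domain Name of the domain whose contact fraction is
#'   reported as `spry_fraction`.
#' @param pae_filter Optional PAE ceiling (Angstrom): when set, a
#'   geometric contact is kept only if both directional PAE entries of
#'   the residue pair lie at or below this value, restricting the
#'   interface to confidently placed residue pairs.
#' @return One-row tibble: `pair_id`, `n_contacts`, `n_salt_bridges`,
#'   `n_polar`, `n_generic`, `spry_fraction` (`NA` when there are no
#'   contacts or no annotation), and a `domain_counts` list column of
#'   per-domain distinct prey contact-residue counts.
#' @export
summarize_interface <- function(pred, annotations = NULL, cutoff = 5.0,
                                salt_bridge_cutoff = 4.0, polar_cutoff = 3.5,
                                spry_domain = "SPRY", pae_filter = NULL) {
  stopifnot(inherits(pred, "complex_prediction"))
  if (is.null(pred$model))
    stop_spry(sprintf("Prediction '%s' carries no structure.", pred$pair_id),
              "missing_structure_error")
  bait_ch <- pred$partition$bait
  prey_ch <- pred$partition$prey
  contacts <- inter_chain_contacts(pred$model, bait_ch, prey_ch, cutoff)
  if (!is.null(pae_filter) && nrow(contacts) > 0L) {
    bi <- partition_range(pred$partition, bait_ch)
    pi <- partition_range(pred$partition, prey_ch)
    v <- pred$pae$values
    keep <- vapply(seq_len(nrow(contacts)), function(k) {
      i <- bi[contacts$resno_a[k]]
      j <- pi[contacts$resno_b[k]]
      max(v[i, j], v[j, i]) <= pae_filter
    }, logical(1))
    contacts <- contacts[keep, , drop = FALSE]
  }
  contacts <- classify_contacts(contacts, pred$model, salt_bridge_cutoff,
                                polar_cutoff)
  prey_res <- unique(contacts$resno_b)
  spry_fraction <- NA_real_
  domain_counts <- tibble(domain = character(), n_residues = integer())
  if (!is.null(annotations)) {
    annotations <- validate_domain_annotations(annotations)
    prey_ann <- annotations[annotations$protein == pred$prey_name, ,
                            drop = FALSE]
    if (nrow(prey_ann) > 0L && length(prey_res) > 0L) {
      doms <- unique(prey_ann$domain)
      domain_counts <- tibble(
        domain = doms,
        n_residues = vapply(doms, function(d) {
          spans <- prey_ann[prey_ann$domain == d, , drop = FALSE]
          sum(vapply(prey_res, function(r)
            any(r >= spans$start & r <= spans$end), logical(1)))
        }, integer(1)))
      if (spry_domain %in% prey_ann$domain)
        spry_fraction <- domain_contact_fraction(
          contacts, annotations, pred$prey_name, spry_domain, prey_ch)
    }
  }
  tibble(
    pair_id = pred$pair_id,
    n_contacts = nrow(contacts),
    n_salt_bridges = sum(contacts$contact_class == "salt_bridge"),
    n_polar = sum(contacts$contact_class == "polar"),
    n_generic = sum(contacts$contact_class == "generic"),
    spry_fraction = spry_fraction,
    domain_counts = list(domain_counts))
}
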
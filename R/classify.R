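#' Default demarcation thresholds
#'
#' Genus separation: AAI 70%, POCP 65%, ANI 74% (AAI is the primary
#' criterion, POCP and ANI corroborate). Species delineation: ANI 95% and
#' AAI 95% (the conservative low end of the commonly cited 95–96% ANI
#' range). 16S rRNA identity thresholds (94.5% genus, 98.65% species) are
#' advisory only and never decisive.
#'
#' @export
GENUS_THRESHOLDS <- c(AAI = 70, POCP = 65, ANI = 74)

#' @rdname GENUS_THRESHOLDS
#' @export
SPECIES_THRESHOLDS <- c(ANI = 95, AAI = 95)

#' @rdname GENUS_THRESHOLDS
#' @export
SSU_ADVISORY <- c(genus = 94.5, species = 98.65)

#' Classify a query genome against labelled references
#'
#' Applies the threshold-based demarcation logic to the pairwise index
#' values of one query genome against a set of labelled reference genomes.
#' The nearest reference per index is the one with the maximal value. The
#' genus call is driven by AAI (the primary criterion): `assigned` when
#' the best AAI reaches the genus threshold and the available corroborating
#' indices (POCP, ANI) agree; `novel_genus` when every available verdict is
#' below threshold; `conflict` when verdicts disagree, with all verdicts
#' listed in the evidence. The species call requires both ANI and AAI at or
#' above their species thresholds against the same reference;
#' `novel_species` when the genus is assigned but the species thresholds
#' are unmet. 16S identity is reported as advisory evidence only.
#'
#' @param query_indices Tibble of the query's pairwise values against the
#'   references: columns `reference`, `index` (`ANI`/`AAI`/`POCP`/`SSU`),
#'   `value`.
#' @param ref_taxonomy Tibble labelling the references: columns
#'   `genome_id`, `genus`, `species`.
#' @param genome_id Id of the query recorded in the result.
#' @param genus_thresholds,species_thresholds,ssu_advisory Named numeric
#'   vectors; see [GENUS_THRESHOLDS].
#' @return A one-row tibble: `genome_id`, `nearest_reference`, best value
#'   per index (`best_ani`, `best_aai`, `best_pocp`, `best_ssu`),
#'   `genus_call`, `species_call`, `evidence`.
#' @export
classify_genome <- function(query_indices, ref_taxonomy,
                            genome_id = "query",
                            genus_thresholds = GENUS_THRESHOLDS,
                            species_thresholds = SPECIES_THRESHOLDS,
                            ssu_advisory = SSU_ADVISORY) {
  qi <- as_tibble(query_indices) %>% filter(!is.na(.data$value))
  if (nrow(qi) == 0L) {
    abort("no index values available for the query")
  }
  if (!all(qi$reference %in% ref_taxonomy$genome_id)) {
    abort("query_indices contains references absent from ref_taxonomy")
  }
  best <- qi %>%
    group_by(.data$index) %>%
    slice_max(.data$value, n = 1, with_ties = FALSE) %>%
    ungroup()
  best_of <- function(ix) {
    row <- best[best$index == ix, ]
    if (nrow(row) == 0) list(value = NA_real_, ref = NA_character_)
    else list(value = row$value, ref = row$reference)
  }
  b_aai <- best_of("AAI")
  b_ani <- best_of("ANI")
  b_pocp <- best_of("POCP")
  b_ssu <- best_of("SSU")

  core <- c(AAI = b_aai$value, POCP = b_pocp$value, ANI = b_ani$value)
  avail <- !is.na(core)
  if (!any(avail)) {
    abort("classification needs at least one of AAI, POCP or ANI")
  }
  verdicts <- core[avail] >= genus_thresholds[names(core)[avail]]
  nearest <- if (!is.na(b_aai$value)) b_aai$ref else
    best$reference[which.max(best$value)][1]
  ref_row <- ref_taxonomy[ref_taxonomy$genome_id == nearest, ]
  verdict_txt <- paste(sprintf("%s=%.1f(%s)", names(core)[avail],
                               core[avail],
                               ifelse(verdicts, "genus", "below")),
                       collapse = "; ")
  evid <- verdict_txt
  if (!is.na(b_ssu$value)) {
    evid <- paste0(evid, sprintf("; SSU=%.1f advisory(%s)", b_ssu$value,
                                 if (b_ssu$value >= ssu_advisory[["genus"]])
                                   "genus-level" else "below-genus"))
  }

  if (all(verdicts)) {
    genus_call <- paste0("assigned:", ref_row$genus)
    sp_ok <- !is.na(b_ani$value) && !is.na(b_aai$value) &&
      b_ani$value >= species_thresholds[["ANI"]] &&
      b_aai$value >= species_thresholds[["AAI"]] &&
      identical(b_ani$ref, b_aai$ref)
    species_call <- if (sp_ok) {
      sp <- ref_taxonomy$species[ref_taxonomy$genome_id == b_ani$ref]
      paste0("assigned:", sp)
    } else "novel_species"
  } else if (all(!verdicts)) {
    genus_call <- "novel_genus"
    species_call <- "n/a"
  } else {
    genus_call <- "conflict"
    species_call <- "n/a"
  }
  tibble(
    genome_id = genome_id,
    nearest_reference = nearest,
    best_ani = b_ani$value, best_aai = b_aai$value,
    best_pocp = b_pocp$value, best_ssu = b_ssu$value,
    genus_call = genus_call, species_call = species_call,
    evidence = evid
  )
}

#' Fuse clustering and tree monophyly into reassignment proposals
#'
#' For every genome, compares its similarity cluster (at the genus
#' threshold) and the monophyly of its labelled genus on the phylogenetic
#' tree against its original labels:
#'
#' * `keep` — the cluster contains exactly the genome's original
#'   genus-mates and the genus is monophyletic;
#' * `novel_genus` — the genome sits in a singleton cluster (below the
#'   genus threshold to everything) on its own branch;
#' * `transfer` — the genus itself is coherent (single cluster,
#'   monophyletic) but nests within another family's clade; the proposal
#'   names the target family and retains the genus (requires a `family`
#'   column in `labels` and the `tree`);
#' * `conflict` — any other disagreement; the evidence names the
#'   cluster-mates' genera so the case can be resolved by eye.
#'
#' @param clusters A `genome_clusters` object (or tibble `genome_id`,
#'   `cluster`).
#' @param monophyly Output of [check_monophyly()] for the genus labelling.
#' @param labels Tibble with columns `genome_id`, `genus` and optionally
#'   `family`.
#' @param tree Optional `phylo` tree (required for family-transfer
#'   detection).
#' @return A tibble: `genome_id`, `original_genus`, `cluster`, `proposal`,
#'   `proposed_genus`, `proposed_family`, `evidence`.
#' @export
consensus_reassignment <- function(clusters, monophyly, labels,
                                   tree = NULL) {
  cl <- if (inherits(clusters, "genome_clusters")) clusters$clusters
        else as_tibble(clusters)
  if (!setequal(cl$genome_id, labels$genome_id)) {
    abort("cluster labels and taxon labels must cover the same genomes")
  }
  if (!is.null(tree) && !setequal(tree$tip.label, cl$genome_id)) {
    abort("tree leaves and cluster labels must cover the same genomes")
  }
  genus <- setNames(labels$genus, labels$genome_id)
  family <- if ("family" %in% names(labels)) {
    setNames(labels$family, labels$genome_id)
  } else NULL
  mono <- setNames(monophyly$monophyletic, monophyly$genus)
  cluster_of <- setNames(cl$cluster, cl$genome_id)

  rows <- lapply(cl$genome_id, function(id) {
    g <- genus[[id]]
    mates <- names(genus)[genus == g]
    members <- names(cluster_of)[cluster_of == cluster_of[[id]]]
    coherent <- setequal(members, mates)
    g_mono <- isTRUE(mono[[g]])
    proposal <- NULL
    proposed_genus <- g
    proposed_family <- if (!is.null(family)) family[[id]] else NA_character_
    evid <- sprintf("cluster={%s}; genus_monophyletic=%s",
                    paste(sort(members), collapse = ","), g_mono)
    if (coherent && g_mono) {
      proposal <- "keep"
      # coherent genus may still sit inside another family's clade
      if (!is.null(family) && !is.null(tree)) {
        fam <- family[[id]]
        fam_leaves <- names(family)[family == fam]
        if (!is_clade(tree, fam_leaves)) {
          others <- setdiff(unique(family), fam)
          for (f2 in others) {
            f2_leaves <- names(family)[family == f2]
            host <- is_clade(tree, sort(union(f2_leaves, mates))) &&
              is_clade(tree, setdiff(fam_leaves, mates))
            if (host) {
              proposal <- "transfer"
              proposed_family <- f2
              evid <- paste0(evid, "; genus nests within family ", f2)
              break
            }
          }
        }
      }
    } else if (length(members) == 1L) {
      proposal <- "novel_genus"
      proposed_genus <- NA_character_
      evid <- paste0(evid, "; singleton cluster below genus threshold")
    } else {
      proposal <- "conflict"
      foreign <- sort(unique(genus[setdiff(members, mates)]))
      evid <- paste0(evid, "; cluster spans genera {",
                     paste(unique(genus[members]), collapse = ","), "}",
                     if (length(foreign) > 0)
                       paste0("; foreign: ", paste(foreign, collapse = ","))
                     else "")
    }
    tibble(genome_id = id, original_genus = g,
           cluster = unname(cluster_of[[id]]), proposal = proposal,
           proposed_genus = proposed_genus,
           proposed_family = proposed_family, evidence = evid)
  })
  bind_rows(rows)
}
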
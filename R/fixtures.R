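#' Specification for synthetic fixture genomes
#'
#' Describes the synthetic genome set used to exercise the whole pipeline
#' without downloading reference databases: per-class genome counts, a
#' genome length range, and the genus structure of the viral records —
#' `n_genera` random ancestors each copied `genomes_per_genus` times with
#' i.i.d. per-site substitution at rate `within_genus_divergence`, emulating
#' a set of closely related phage genomes.
#'
#' @param n_per_class named counts per class label (names from
#'   [genome_classes()]); classes may be omitted (count 0)
#' @param genome_length_range two integers, min and max genome length in bp
#' @param n_genera,genomes_per_genus viral genus structure; viral genomes
#'   are `n_genera * genomes_per_genus` in total, overriding any `viral`
#'   entry of `n_per_class` when both are given (`n_per_class["viral"]`
#'   is used only when `n_genera` is `NULL`)
#' @param within_genus_divergence substitution probability per site within
#'   a genus, in \[0, 0.5\] (default 0.05)
#' @param seed RNG seed; all fixture generation is a pure function of the
#'   spec and this seed
#' @return a list of class `"fixture_spec"`
#' @export
fixture_spec <- function(n_per_class = c(viral = 12, prokaryote = 6,
                                         eukaryote = 2, plasmid = 2, archaea = 0),
                         genome_length_range = c(30000L, 60000L),
                         n_genera = 3L, genomes_per_genus = 4L,
                         within_genus_divergence = 0.05,
                         seed = 1L) {
  stopifnot(all(names(n_per_class) %in% genome_classes()),
            length(genome_length_range) == 2L,
            genome_length_range[1] <= genome_length_range[2],
            within_genus_divergence >= 0, within_genus_divergence <= 0.5)
  structure(
    list(n_per_class = n_per_class,
         genome_length_range = as.integer(genome_length_range),
         n_genera = if (is.null(n_genera)) NULL else as.integer(n_genera),
         genomes_per_genus = as.integer(genomes_per_genus),
         within_genus_divergence = within_genus_divergence,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, p) {
  if (p == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(bases)) < p
  if (any(hit)) {
    # substitute with a uniformly chosen *different* base
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

#' Generate labeled synthetic genomes
#'
#' Produces a genome tibble (see [validate_genomes()]) from a
#' [fixture_spec()]: uniform-random A/C/G/T sequences for the cellular,
#' plasmid and archaeal classes, and genus-structured viral genomes
#' (ancestor copies with per-site substitution). Deterministic under the
#' spec's seed.
#'
#' @param spec a [fixture_spec()]
#' @return a genome tibble with `genus` set on viral records
#' @examples
#' g <- make_genomes(fixture_spec(seed = 7))
#' dplyr::count(g, class_label)
#' @export
make_genomes <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  rng <- spec$genome_length_range
  rand_len <- function() sample(rng[1]:rng[2], 1L)

  rows <- list()
  if (!is.null(spec$n_genera) && spec$n_genera > 0) {
    for (gi in seq_len(spec$n_genera)) {
      ancestor <- random_sequence(rand_len())
      genus <- sprintf("genus_%02d", gi)
      for (k in seq_len(spec$genomes_per_genus)) {
        seqk <- if (k == 1L) ancestor else
          mutate_sequence(ancestor, spec$within_genus_divergence)
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("viral_%s_g%d", genus, k), sequence = seqk,
          class_label = "viral", genus = genus, circular = FALSE
        )
      }
    }
  } else {
    n_viral <- spec$n_per_class[["viral"]] %||% 0
    for (k in seq_len(n_viral)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("viral_%03d", k), sequence = random_sequence(rand_len()),
        class_label = "viral", genus = NA_character_, circular = FALSE
      )
    }
  }
  for (cls in setdiff(genome_classes(), "viral")) {
    n <- spec$n_per_class[cls]
    n <- if (is.na(n) || is.null(n)) 0L else as.integer(n)
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("%s_%03d", cls, k), sequence = random_sequence(rand_len()),
        class_label = cls, genus = NA_character_, circular = FALSE
      )
    }
  }
  out <- bind_rows(rows)
  validate_genomes(out)
  out
}

#' Simulate identification-tool predictions with known error rates
#'
#' Emulates a virus-identification tool with configured per-length
#' sensitivity and false-positive rate: each viral fragment is called viral
#' with probability `sensitivity[L]`, each non-viral fragment with
#' probability `fpr[L]`, independently. Downstream scoring of these calls
#' must recover the configured rates, which makes this the package's
#' parameter-recovery harness.
#'
#' @param truth truth table with `fragment_id`, `is_viral`, `length_class`
#' @param sensitivity named numeric vector: per-length true-positive call
#'   probability (names = fragment lengths)
#' @param fpr named numeric vector: per-length false-positive call
#'   probability
#' @param seed RNG seed
#' @return character vector of fragment ids called viral
#' @export
simulate_predictions <- function(truth, sensitivity, fpr, seed = 1L) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(fpr >= 0 & fpr <= 1))
  lens <- as.character(unique(truth$length_class))
  missing <- setdiff(lens, intersect(names(sensitivity), names(fpr)))
  if (length(missing)) {
    abort(paste0("no sensitivity/fpr entry for length ", paste(missing, collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  is_viral <- as.logical(truth$is_viral)
  p <- ifelse(is_viral,
              sensitivity[as.character(truth$length_class)],
              fpr[as.character(truth$length_class)])
  called <- stats::runif(nrow(truth)) < p
  truth$fragment_id[called]
}

#' Simulate a gene-sharing-network clustering with a known error rate
#'
#' Maps each truth genus to one cluster, places one reference genome per
#' genus in its cluster, and assigns each fragment to its own genus's
#' cluster with probability `1 - error_rate`, otherwise to a uniformly
#' chosen *other* cluster. An `error_rate` of 0 therefore yields a perfect
#' clustering (all clustering-wise metrics equal 1).
#'
#' @param truth truth table with `fragment_id` and `genus` (rows with `NA`
#'   genus are ignored)
#' @param error_rate misassignment probability in \[0, 1\]
#' @param seed RNG seed
#' @return an assignment tibble (see [validate_assignments()]) containing
#'   the fragments plus one reference row per genus
#' @export
simulate_clustering <- function(truth, error_rate = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  frags <- filter(as_tibble(truth), !is.na(.data$genus))
  genera <- sort(unique(frags$genus))
  clusters <- setNames(paste0("VC_", seq_along(genera)), genera)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  assigned <- vapply(frags$genus, function(g) {
    if (length(genera) > 1L && stats::runif(1) < error_rate) {
      sample(setdiff(unname(clusters), clusters[[g]]), 1L)
    } else {
      clusters[[g]]
    }
  }, character(1))
  bind_rows(
    tibble(item_id = frags$fragment_id, cluster_id = unname(assigned),
           status = "clustered", is_reference = FALSE, genus = frags$genus),
    tibble(item_id = paste0("ref_", genera), cluster_id = unname(clusters),
           status = "clustered", is_reference = TRUE, genus = genera)
  )
}

#' The five AMG genomic-context archetype contigs
#'
#' Builds the canonical test set for [triage_report()]: five annotated
#' contigs, each a minimal embodiment of one genomic-context situation a
#' curator meets when vetting candidate AMGs.
#'
#' * `contig_1` — hallmark-rich neighborhood, closely related to a known
#'   phage: `likely_viral`.
#' * `contig_2` — viral/unknown gene content, no known-phage similarity:
#'   `possible_viral`.
#' * `contig_3` — a long (~120 kbp) region of dense short cellular/unknown
#'   genes with zero viral or viral-like genes, the profile of a cellular
#'   region or mobile genetic element: `unlikely_viral`.
#' * `contig_4` — the candidate AMG sits in a neighborhood with little
#'   evidence of viral origin although the contig as a whole was called
#'   viral: `unlikely_viral`.
#' * `contig_5` — the candidate AMG lies at the contig edge next to a tRNA
#'   and a phage integrase, the signature of a miscalled prophage boundary:
#'   `unlikely_viral`.
#'
#' @return a list with tibbles `genes` and `contigs` ready for
#'   [triage_report()]
#' @examples
#' arch <- make_amg_archetypes()
#' triage_report(arch$genes, arch$contigs)
#' @export
make_amg_archetypes <- function() {
  gene_row <- function(contig_id, idx, category, is_amg = FALSE,
                       amg_score = NA_integer_, len = 900L, gap = 100L) {
    start <- (idx - 1L) * (len + gap)
    tibble(contig_id = contig_id, gene_index = idx,
           start = start, end = start + len,
           strand = if (idx %% 2 == 0) "-" else "+",
           category = category, is_amg = is_amg,
           amg_score = amg_score,
           amg_flags = if (is_amg) "M" else NA_character_)
  }
  contig_genes <- function(contig_id, categories, amg_at, amg_score = 2L,
                           len = 900L, gap = 100L) {
    purrr::imap(categories, function(cat, i) {
      gene_row(contig_id, i, cat, is_amg = (i == amg_at),
               amg_score = if (i == amg_at) amg_score else NA_integer_,
               len = len, gap = gap)
    }) |> bind_rows()
  }

  # contig_1: mostly hallmark/viral-like around a central AMG
  c1 <- contig_genes("contig_1",
                     c("viral_hallmark", "viral_like", "viral_hallmark", "unknown",
                       "viral_hallmark", "cellular", "viral_like", "viral_hallmark",
                       "unknown", "viral_hallmark", "viral_like"),
                     amg_at = 6L)
  # contig_2: viral-like and unknown genes, central AMG
  c2 <- contig_genes("contig_2",
                     c("unknown", "viral_like", "unknown", "unknown", "viral_like",
                       "cellular", "unknown", "viral_like", "unknown", "unknown",
                       "viral_like"),
                     amg_at = 6L)
  # contig_3: ~120 kbp of dense, short cellular/unknown genes, zero viral
  c3_cats <- rep(c("cellular", "cellular", "unknown"), length.out = 150L)
  c3_amg_at <- 75L
  c3_cats[c3_amg_at] <- "cellular"
  c3 <- contig_genes("contig_3", c3_cats, amg_at = c3_amg_at,
                     len = 700L, gap = 100L)
  # contig_4: viral genes exist on the contig, but the AMG neighborhood is
  # dominated by cellular genes
  c4 <- contig_genes("contig_4",
                     c("viral_hallmark", "viral_like", "viral_hallmark", "unknown",
                       "viral_like", "cellular", "cellular", "cellular",
                       "cellular", "cellular", "cellular", "cellular",
                       "cellular", "cellular", "viral_like", "unknown"),
                     amg_at = 10L)
  # contig_5: AMG at the edge, tRNA and integrase immediately inboard
  c5 <- contig_genes("contig_5",
                     c("cellular", "tRNA", "integrase", "viral_like",
                       "viral_hallmark", "unknown", "viral_hallmark", "viral_like",
                       "unknown", "viral_hallmark", "viral_like", "viral_hallmark",
                       "unknown", "viral_hallmark", "viral_like", "unknown",
                       "viral_hallmark", "viral_like", "unknown", "viral_hallmark"),
                     amg_at = 1L)

  genes <- bind_rows(c1, c2, c3, c4, c5)
  contig_len <- genes |>
    group_by(.data$contig_id) |>
    summarise(length_bp = max(.data$end) + 100L, .groups = "drop")
  contigs <- contig_len |>
    mutate(
      circular = FALSE,
      known_phage_similarity = .data$contig_id == "contig_1",
      virsorter_category = ifelse(.data$contig_id == "contig_3", NA_real_, 1),
      dvf_score = 0.95, dvf_pvalue = 0.01
    )
  list(genes = genes, contigs = contigs)
}
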
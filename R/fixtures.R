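# Deterministic generator of toy multi-genome protein collections with
# known ortholog/paralog structure, annotations and publications, so the
# whole pipeline is testable offline against a recorded truth table.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Fixture generator configuration
#'
#' Defaults describe a small but structurally complete study system: five
#' genomes, three families of length-200 proteins spanning all genomes,
#' orthologs mutated to 90% identity of the family ancestor (pairwise
#' ortholog identity then lands near 81%), one within-genome paralog per
#' family at 55% (the classic annotation-transfer confounder), one
#' cross-family decoy per family at 30% (homologous enough to be detected,
#' too remote for reliable transfer), one 99%-identity allele of the first
#' family's genome-2 ortholog (exercises cluster-aware reciprocal best
#' hits), two unrelated random decoys, and one mega-publication linked to
#' 150 protein records (exercises the large-scale-study exclusion).
#'
#' @param n_genomes Number of genomes.
#' @param n_families Number of protein families.
#' @param family_sizes Integer vector: how many genomes each family spans
#'   (genome 1 upward); default all of them.
#' @param ortholog_identity_target Percent identity of each ortholog to the
#'   family ancestor.
#' @param paralog_identity_target Percent identity of the within-genome
#'   paralog to the family ancestor.
#' @param cross_decoy_identity_target Percent identity of the cross-family
#'   decoy to the family ancestor.
#' @param decoy_count Number of unrelated random decoy sequences.
#' @param seq_length Ancestor sequence length in residues.
#' @param mega_publication_size `n_linked_proteins` of the planted
#'   large-scale publication (> 100 so it is excluded).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_genomes = 5, n_families = 3,
                           family_sizes = NULL,
                           ortholog_identity_target = 90,
                           paralog_identity_target = 55,
                           cross_decoy_identity_target = 30,
                           decoy_count = 2, seq_length = 200,
                           mega_publication_size = 150, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(family_sizes)) family_sizes <- rep(n_genomes, n_families)
  if (length(family_sizes) != n_families) {
    stop("family_sizes must have one entry per family")
  }
  if (any(family_sizes < 1) || any(family_sizes > n_genomes)) {
    stop("family_sizes must lie in 1..n_genomes")
  }
  stopifnot(ortholog_identity_target > 0, ortholog_identity_target <= 100,
            paralog_identity_target > 0, paralog_identity_target <= 100,
            decoy_count >= 0, seq_length >= 10)
  structure(list(n_genomes = n_genomes, n_families = n_families,
                 family_sizes = as.integer(family_sizes),
                 ortholog_identity_target = ortholog_identity_target,
                 paralog_identity_target = paralog_identity_target,
                 cross_decoy_identity_target = cross_decoy_identity_target,
                 decoy_count = as.integer(decoy_count),
                 seq_length = as.integer(seq_length),
                 mega_publication_size = as.integer(mega_publication_size),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Mutate a sequence to a target identity
#'
#' Substitutes `round(len * (1 - target/100))` positions, chosen without
#' replacement, each with a residue drawn uniformly from the 19
#' alternatives. Length is preserved; no indels, so the realized identity
#' of a full-length alignment equals the target up to rounding.
#'
#' @param seq Residue string.
#' @param target_identity Target percent identity in `(0, 100]`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (for calls inside a seeded generator).
#' @return The mutated residue string.
#' @export
mutate_sequence <- function(seq, target_identity, seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (!is.null(seed)) return(with_seed(seed, mutate_sequence(seq,
                                                             target_identity)))
  len <- nchar(seq)
  n_sub <- round(len * (1 - target_identity / 100))
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(len, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic multi-genome fixture collection
#'
#' Builds the full input set for a pipeline run -- FASTA collection plus the
#' three sidecar tables -- together with family/subgroup labels and a truth
#' table of expected reciprocal-best-hit verdicts. Per family: one random
#' ancestor; one ortholog per spanned genome at the ortholog identity
#' target; a paralog in genome 2 at the paralog target; a cross-family
#' decoy in genome 3 at the decoy target (flagged as a reference so it
#' exercises low-score behaviour). Genome-1 orthologs are the designated
#' queries and carry no annotation. Reference orthologs receive one to
#' three publications with seeded dates; the first family's genome-4
#' ortholog is linked only to the mega-publication (and so is excluded from
#' candidacy); a 99% allele of the first family's genome-2 ortholog is
#' planted unannotated. Output is byte-identical for identical
#' configurations.
#'
#' @param config A [fixture_config()] object.
#' @param dir Output directory (created if needed); when `NULL` nothing is
#'   written and only in-memory objects are returned.
#' @return A list: `seqs`, `annotations`, `publications`, `genome_table`,
#'   `labels`, `truth`, `query_ids`, and (when `dir` is given) `paths`.
#' @export
generate_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    seqs <- list(); links <- list(); labels <- list(); truth <- list()
    pubs <- list(); genome_rows <- list()
    pm_counter <- 0L
    new_pub <- function() {
      pm_counter <<- pm_counter + 1L
      pmid <- sprintf("PM%04d", pm_counter)
      date <- as.Date("2000-01-01") + sample.int(5800, 1)
      pubs[[length(pubs) + 1L]] <<- data.frame(
        pmid = pmid, date = format(date, "%Y-%m-%d"),
        n_linked_proteins = sample.int(5, 1), stringsAsFactors = FALSE)
      pmid
    }
    add_seq <- function(id, residues, genome, family, subgroup,
                        pubmed = character(0), sp = FALSE, pdb = FALSE,
                        description = "") {
      seqs[[length(seqs) + 1L]] <<- data.frame(
        protein_id = id, description = description,
        taxon = genome, residues = residues, stringsAsFactors = FALSE)
      genome_rows[[length(genome_rows) + 1L]] <<- data.frame(
        protein_id = id, taxon = genome, stringsAsFactors = FALSE)
      links[[length(links) + 1L]] <<- data.frame(
        protein_id = id, pubmed_ids = paste(pubmed, collapse = ";"),
        in_swissprot = as.integer(sp), in_pdb = as.integer(pdb),
        description = description, stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <<- data.frame(
        protein_id = id, family = family, subgroup = subgroup,
        stringsAsFactors = FALSE)
    }
    add_truth <- function(query, cand, relation, q2h, h2q, is_cand) {
      truth[[length(truth) + 1L]] <<- data.frame(
        query_id = query, candidate_id = cand, relation = relation,
        expected_q2h = q2h, expected_h2q = h2q,
        is_candidate = is_cand, stringsAsFactors = FALSE)
    }

    mega_pmid <- "PM9999"
    pubs[[length(pubs) + 1L]] <- data.frame(
      pmid = mega_pmid, date = "2010-06-15",
      n_linked_proteins = config$mega_publication_size,
      stringsAsFactors = FALSE)

    query_ids <- character(0)
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("F%d", f)
      subgroup <- sprintf("S%d", ceiling(f / 2))
      ancestor <- random_sequence(config$seq_length)
      size <- config$family_sizes[f]
      query_id <- sprintf("%s_G1", fam)
      for (g in seq_len(size)) {
        id <- sprintf("%s_G%d", fam, g)
        res <- mutate_sequence(ancestor, config$ortholog_identity_target)
        genome <- sprintf("G%d", g)
        if (g == 1) {
          # the designated query: unannotated on purpose
          add_seq(id, res, genome, fam, subgroup,
                  description = sprintf("family %s query protein", fam))
          query_ids <- c(query_ids, id)
        } else if (f == 1 && g == 4) {
          # linked only to the mega-publication: not a usable reference
          add_seq(id, res, genome, fam, subgroup, pubmed = mega_pmid,
                  description = sprintf("%s ortholog, large-scale study only",
                                        fam))
          add_truth(query_id, id, "ortholog", "true", "true", FALSE)
          next
        } else {
          pmids <- vapply(seq_len(sample.int(3, 1)), function(k) new_pub(),
                          character(1))
          if (f == 1 && g == 2) pmids <- c(pmids, mega_pmid)
          add_seq(id, res, genome, fam, subgroup, pubmed = pmids,
                  sp = runif(1) < 0.5, pdb = runif(1) < 0.3,
                  description = sprintf("%s ortholog, characterized", fam))
        }
        if (g > 1) add_truth(query_id, id, "ortholog", "true", "true", TRUE)
      }
      if (size >= 2) {
        par_id <- sprintf("%s_G2_par", fam)
        add_seq(par_id,
                mutate_sequence(ancestor, config$paralog_identity_target),
                "G2", paste0(fam, "par"), subgroup, sp = TRUE,
                description = sprintf("%s-related paralog", fam))
        add_truth(query_id, par_id, "paralog", "false", "true", TRUE)
      }
      if (size >= 3) {
        x_id <- sprintf("%s_X", fam)
        add_seq(x_id,
                mutate_sequence(ancestor,
                                config$cross_decoy_identity_target),
                "G3", paste0(fam, "x"), "SX", pubmed = new_pub(),
                description = sprintf("remote homolog of %s, other family",
                                      fam))
        add_truth(query_id, x_id, "cross_decoy", "false", "true", TRUE)
      }
      if (f == 1 && size >= 2) {
        base <- seqs[[which(vapply(seqs, function(s)
          s$protein_id == "F1_G2", logical(1)))]]$residues
        add_seq("F1_G2_allele", mutate_sequence(base, 99), "G2", fam,
                subgroup, description = "allelic variant of F1_G2")
      }
    }
    for (d in seq_len(config$decoy_count)) {
      add_seq(sprintf("DEC%d", d), random_sequence(config$seq_length),
              sprintf("G%d", ((d - 1) %% config$n_genomes) + 1),
              "DEC", "SDEC", description = "unrelated decoy")
    }

    out <- list(
      seqs = do.call(rbind, seqs),
      annotations = NULL,  # filled below from the links frame
      publications = NULL,
      genome_table = do.call(rbind, genome_rows),
      labels = do.call(rbind, labels),
      truth = do.call(rbind, truth),
      query_ids = query_ids
    )
    links_df <- do.call(rbind, links)
    pubs_df <- do.call(rbind, pubs)
    out$annotations <- data.frame(protein_id = links_df$protein_id,
                                  stringsAsFactors = FALSE)
    out$annotations$pubmed_ids <-
      lapply(strsplit(links_df$pubmed_ids, ";", fixed = TRUE),
             function(x) x[nzchar(x)])
    out$annotations$in_swissprot <- links_df$in_swissprot == 1L
    out$annotations$in_pdb <- links_df$in_pdb == 1L
    out$annotations$description <- links_df$description
    out$publications <- data.frame(pmid = pubs_df$pmid,
                                   date = as.Date(pubs_df$date),
                                   n_linked_proteins =
                                     as.integer(pubs_df$n_linked_proteins),
                                   stringsAsFactors = FALSE)

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        fasta = file.path(dir, "collection.fasta"),
        links = file.path(dir, "links.tsv"),
        pubs = file.path(dir, "pubs.tsv"),
        genomes = file.path(dir, "genomes.tsv"),
        labels = file.path(dir, "labels.tsv"),
        truth = file.path(dir, "truth.tsv")
      )
      write_fasta(out$seqs, paths$fasta)
      wt <- function(df, path) write.table(df, path, sep = "\t",
                                           quote = FALSE, row.names = FALSE)
      wt(links_df, paths$links)
      wt(pubs_df, paths$pubs)
      wt(out$genome_table, paths$genomes)
      wt(out$labels, paths$labels)
      wt(out$truth, paths$truth)
      out$paths <- paths
    }
    out
  })
}
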
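translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
}

#' The field catalog of SDH target-site substitutions
#'
#' Loads the curated catalog of the 15 amino-acid substitutions observed in
#' the acaricide target genes: six changes on five residues of \emph{sdhB}
#' (H146Q, S212I, H258Y, I260T, I260V, A285S) and nine changes on three
#' residues of \emph{sdhD} (D116G, D116E, D116N, R119C, R119L, R119G,
#' R119P, R119H, P120L).  D116E is stored as two rows (wild codons GAC and
#' GAT, each a single-nucleotide change to GAA) sharing one label and
#' counting once towards the 15.  The catalog is validated on load:
#' translations must match the amino acids, every wild/mutant codon pair
#' must differ at exactly one position, and labels must equal
#' wild_aa + residue + mutant_aa.
#'
#' @return data.frame with columns gene, residue, wild_codon, mutant_codon,
#'   wild_aa, mutant_aa, label, first_detected_year.
#' @export
load_catalog <- function() {
  path <- system.file("extdata", "sdh_target_mutations.tsv",
                      package = "mitesweep", mustWork = TRUE)
  cat_ <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  with(cat_, {
    if (!all(translate_codon(wild_codon) == wild_aa) ||
        !all(translate_codon(mutant_codon) == mutant_aa))
      stop("catalog validation failed: codon/amino-acid mismatch")
    ndiff <- mapply(function(a, b)
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), wild_codon, mutant_codon)
    if (!all(ndiff == 1L))
      stop("catalog validation failed: non-single-nucleotide codon change")
    if (!all(label == paste0(wild_aa, residue, mutant_aa)))
      stop("catalog validation failed: label mismatch")
  })
  if (length(unique(cat_$label)) != 15L)
    stop("catalog validation failed: expected 15 distinct substitutions")
  cat_
}

#' Build a two-exon-free coding gene model
#'
#' A minimal gene model for codon-level annotation: CDS intervals on a
#' chromosome, strand, and the reference coding sequence (already
#' strand-oriented, i.e. the mRNA sense).
#'
#' @param gene gene id (e.g. "sdhB").
#' @param chrom chromosome.
#' @param cds_start,cds_end 1-based inclusive CDS interval vectors (one
#'   element per exon, in genomic order).
#' @param strand "+" or "-".
#' @param cds_seq the coding sequence, 5' to 3' on the coding strand.
#' @return object of class \code{gene_model}.
#' @export
gene_model <- function(gene, chrom, cds_start, cds_end, strand = "+", cds_seq) {
  stopifnot(length(cds_start) == length(cds_end), all(cds_end >= cds_start),
            strand %in% c("+", "-"))
  len <- sum(cds_end - cds_start + 1L)
  if (nchar(cds_seq) != len) stop("cds_seq length does not match CDS intervals")
  if (len %% 3L != 0L) stop("CDS length must be divisible by 3")
  prot <- translate_codon(substring(cds_seq, seq(1, len, 3), seq(3, len, 3)))
  if (any(prot[-length(prot)] == "*")) stop("internal stop codon in CDS")
  structure(list(gene = gene, chrom = chrom, cds_start = cds_start,
                 cds_end = cds_end, strand = strand,
                 cds_seq = toupper(cds_seq)),
            class = "gene_model")
}

# genomic position -> 1-based offset in the coding sequence (NA outside CDS)
cds_offset <- function(model, pos) {
  starts <- model$cds_start; ends <- model$cds_end
  widths <- ends - starts + 1L
  hit <- which(pos >= starts & pos <= ends)
  if (length(hit) == 0L) return(NA_integer_)
  within <- pos - starts[hit] + 1L
  fwd <- sum(widths[seq_len(hit - 1L)]) + within
  if (model$strand == "+") fwd else sum(widths) - fwd + 1L
}

#' Codon-level annotation of a SNP within a gene model
#'
#' Maps a genomic position to its codon and intra-codon offset
#' (strand-aware), substitutes the observed alternate base, and reports the
#' amino-acid change in standard label form (e.g. "I260V"), or
#' "synonymous" / "non-coding".
#'
#' @param pos genomic position (1-based).
#' @param ref,alt observed reference and alternate bases on the genomic
#'   forward strand.
#' @param model a \code{\link{gene_model}}.
#' @return list: gene, residue, codon_pos (1-3), wild_codon, mutant_codon,
#'   wild_aa, mutant_aa, effect ("missense", "synonymous", "nonsense" or
#'   "non-coding"), label (NA unless missense/nonsense).
#' @export
annotate_snp <- function(pos, ref, alt, model) {
  stopifnot(inherits(model, "gene_model"))
  off <- cds_offset(model, pos)
  if (is.na(off))
    return(list(gene = model$gene, residue = NA_integer_,
                codon_pos = NA_integer_, wild_codon = NA_character_,
                mutant_codon = NA_character_, wild_aa = NA_character_,
                mutant_aa = NA_character_, effect = "non-coding",
                label = NA_character_))
  ref_c <- toupper(ref); alt_c <- toupper(alt)
  if (model$strand == "-") { ref_c <- revcomp(ref_c); alt_c <- revcomp(alt_c) }
  model_base <- substr(model$cds_seq, off, off)
  if (model_base != ref_c)
    stop(sprintf("reference base mismatch at CDS offset %d: model has %s, got %s",
                 off, model_base, ref_c))
  residue <- (off - 1L) %/% 3L + 1L
  codon_pos <- (off - 1L) %% 3L + 1L
  codon_start <- (residue - 1L) * 3L + 1L
  wild <- substr(model$cds_seq, codon_start, codon_start + 2L)
  mut <- wild
  substr(mut, codon_pos, codon_pos) <- alt_c
  wild_aa <- translate_codon(wild); mut_aa <- translate_codon(mut)
  effect <- if (mut_aa == wild_aa) "synonymous"
            else if (mut_aa == "*") "nonsense" else "missense"
  list(gene = model$gene, residue = residue, codon_pos = codon_pos,
       wild_codon = wild, mutant_codon = mut, wild_aa = wild_aa,
       mutant_aa = mut_aa, effect = effect,
       label = if (effect == "synonymous") paste0(wild_aa, residue, wild_aa)
               else paste0(wild_aa, residue, mut_aa))
}

#' All single-nucleotide neighbours of a codon
#'
#' Enumerates the nine codons one substitution away, with their
#' translations and stop flags — the raw material of the codon-saturation
#' argument (how many of the accessible missense changes at a residue have
#' actually been observed in the field).
#'
#' @param codon a trinucleotide.
#' @return data.frame of 9 rows: position (1-3), from, to, mutant_codon,
#'   mutant_aa, is_stop, is_synonymous.
#' @export
accessible_substitutions <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) stop("invalid codon")
  wild_aa <- translate_codon(codon)
  rows <- list()
  for (p in 1:3) {
    from <- substr(codon, p, p)
    for (to in setdiff(c("A", "C", "G", "T"), from)) {
      mut <- codon
      substr(mut, p, p) <- to
      aa <- translate_codon(mut)
      rows[[length(rows) + 1L]] <-
        data.frame(position = p, from = from, to = to, mutant_codon = mut,
                   mutant_aa = aa, is_stop = aa == "*",
                   is_synonymous = aa == wild_aa)
    }
  }
  do.call(rbind, rows)
}

#' Per-population mutation counts and year-group means
#'
#' A mutation is "present" in a population when its frequency exceeds the
#' presence threshold (default 0, i.e. any detection by either data type).
#'
#' @param freqs data.frame with columns population, year, mutation,
#'   frequency.
#' @param threshold presence threshold on frequency (strictly greater
#'   than).
#' @return list: \code{per_population} (population, year, n_mutations) and
#'   \code{per_year} (year, mean_mutations, n_populations).
#' @export
population_mutation_summary <- function(freqs, threshold = 0) {
  stopifnot(all(c("population", "year", "mutation", "frequency") %in% names(freqs)))
  if (any(is.na(freqs$year))) stop("unknown year label")
  present <- freqs$frequency > threshold
  per_pop <- stats::aggregate(present, by = list(population = freqs$population,
                                                 year = freqs$year), FUN = sum)
  names(per_pop)[3L] <- "n_mutations"
  per_year <- stats::aggregate(per_pop$n_mutations,
                               by = list(year = per_pop$year), FUN = mean)
  names(per_year)[2L] <- "mean_mutations"
  per_year$n_populations <- as.vector(table(per_pop$year)[as.character(per_year$year)])
  list(per_population = per_pop, per_year = per_year)
}
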
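#' Protein-domain annotation of mutated residues
#'
#' Maps mutated residues onto the domain architecture (FERM, SH2, SH2-JH2
#' linker, JH2 pseudokinase, JH1 kinase for JAKs; coiled-coil, DNA-binding,
#' SH2, transactivation for STATs) and summarizes where a gene's mutations
#' cluster. Mutations are counted per occurrence: a case carrying two SH2
#' mutations contributes two.
#'
#' @name protein-domains
NULL

#' Annotate one or more residues with their protein domain
#'
#' @param model Domain model table ([domainModels()]).
#' @param gene Gene symbol (must be present in the model).
#' @param residue Integer residue position(s), 1-based.
#' @return Character vector of domain labels; residues outside every interval
#'   get `"inter-domain"`.
#' @examples
#' annotateDomain(domainModels(), "STAT5B", 642)
#' @export
annotateDomain <- function(model, gene, residue) {
  sub <- model[model$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("gene %s absent from the domain model", gene)
  if (any(residue < 1L)) stopf("residue positions must be >= 1")
  vapply(residue, function(r) {
    hit <- which(r >= sub$aa_start & r <= sub$aa_end)
    if (length(hit) == 1L) sub$domain[hit] else "inter-domain"
  }, "")
}

#' Domain distribution of a gene's mutations
#'
#' @param calls Harmonized calls (with `protein_change`).
#' @param model Domain model table.
#' @param gene Gene symbol.
#' @param variant_class Class filter; default `"missense"` (use `NULL` for
#'   all classes).
#' @return Named list of [newFrequency()] objects, one per observed domain
#'   label over the total qualifying mutation count; fractions sum to 1.
#' @export
domainDistribution <- function(calls, model = domainModels(), gene,
                               variant_class = "missense") {
  sub <- calls[calls$gene == gene, , drop = FALSE]
  if (!is.null(variant_class))
    sub <- sub[sub$variant_class %in% variant_class, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("no qualifying mutations for %s", gene)
  res <- parseProteinChange(sub$protein_change)$position
  labels <- annotateDomain(model, gene, res)
  counts <- table(labels)
  out <- lapply(as.integer(counts), newFrequency, denominator = nrow(sub))
  names(out) <- names(counts)
  out
}

#' Lollipop-style coordinate export for plotting
#'
#' @param calls Harmonized calls.
#' @param model Domain model table.
#' @param gene Gene symbol.
#' @return data.frame with one row per distinct lesion: protein_change,
#'   position, domain, occurrences.
#' @export
lollipopTable <- function(calls, model = domainModels(), gene) {
  sub <- calls[calls$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(protein_change = character(0), position = integer(0),
                      domain = character(0), occurrences = integer(0)))
  res <- parseProteinChange(sub$protein_change)$position
  agg <- table(sub$protein_change)
  pos <- parseProteinChange(names(agg))$position
  out <- data.frame(protein_change = names(agg), position = pos,
                    domain = annotateDomain(model, gene, pos),
                    occurrences = as.integer(agg), stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}
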
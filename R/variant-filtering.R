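# Dataset-construction rules: indel typing, clinical/population/genotype
# filters, training-overlap exclusion and the ProGen2-style sequence window.
# Every filter returns both the kept records and a per-rule audit, so
# dataset sizes can be reported rule by rule.

new_filter_audit <- function(rules, n_in, n_kept) {
  stopifnot(length(rules) == length(n_in), length(n_in) == length(n_kept))
  structure(list(table = data.frame(rule = rules, n_in = n_in, n_kept = n_kept,
                                    stringsAsFactors = FALSE),
                 final_kept = if (length(n_kept)) n_kept[length(n_kept)] else NA_integer_),
            class = "filter_audit")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("<filter_audit>\n")
  print(x$table, row.names = FALSE)
  cat("final kept:", x$final_kept, "\n")
  invisible(x)
}

#' Type an indel by its net effect on sequence length
#'
#' Complex indels (both alleles longer than one base) are typed by the net
#' length change alone: `net_nt = nchar(alt) - nchar(ref)`. A variant is
#' in-frame when the net change is a multiple of 3; a zero net change is
#' typed `"balanced"` and takes no part in insertion/deletion calibration.
#'
#' @param ref_allele,alt_allele Non-empty uppercase ACGT strings (vectorised).
#' @return A data frame with columns `kind` (`insertion`/`deletion`/
#'   `balanced`), `net_nt` (signed nucleotides) and `in_frame`.
#' @examples
#' classify_indel("ATG", "A")     # deletion, net -2, frameshift
#' classify_indel("A", "ATTT")    # insertion, net +3, in-frame
#' classify_indel("AT", "GCCAT")  # complex, typed as +3 insertion
#' @export
classify_indel <- function(ref_allele, alt_allele) {
  if (length(ref_allele) != length(alt_allele))
    abort_input("ref and alt allele vectors must have equal length")
  bad <- !nzchar(ref_allele) | !nzchar(alt_allele) | is.na(ref_allele) | is.na(alt_allele)
  if (any(bad)) abort_input("empty or missing allele string")
  if (any(grepl("[^ACGT]", c(ref_allele, alt_allele))))
    abort_input("alleles must be uppercase ACGT strings")
  net <- nchar(alt_allele) - nchar(ref_allele)
  data.frame(kind = ifelse(net > 0L, "insertion",
                    ifelse(net < 0L, "deletion", "balanced")),
             net_nt = net,
             in_frame = net %% 3L == 0L,
             stringsAsFactors = FALSE)
}

check_classification_tokens <- function(records) {
  valid <- c("P", "P/LP", "LP", "B", "B/LB", "LB", "VUS", "conflicting", "none")
  bad <- which(!records$classification %in% valid)
  if (length(bad)) {
    id <- if ("variant_id" %in% names(records)) records$variant_id[bad[1]]
          else paste0("row ", bad[1])
    abort_input(sprintf("unknown classification token '%s' in record %s",
                        records$classification[bad[1]], id))
  }
}

apply_rule_chain <- function(records, rules) {
  alive <- rep(TRUE, nrow(records))
  n_in <- n_kept <- integer(length(rules))
  for (j in seq_along(rules)) {
    n_in[j] <- sum(alive)
    alive <- alive & rules[[j]]
    n_kept[j] <- sum(alive)
  }
  kept <- records[alive, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, audit = new_filter_audit(names(rules), n_in, n_kept))
}

#' Clinical (ClinVar-style) variant filter
#'
#' Applies, in order: disease-gene validity tier (definitive/strong/moderate),
#' review status (at least one star, no conflicting assertions), global allele
#' frequency (missing, i.e. absent from the population database, or <= 1%),
#' net indel length <= 50 bp, an unambiguous clinical classification
#' (P, P/LP, LP, B, B/LB or LB), and in-frame net length change. Rule order
#' affects only the per-rule audit counts; the final kept set is the
#' intersection of all rules.
#'
#' @param records Variant data frame carrying `gene_validity`,
#'   `review_stars`, `has_conflict`, `allele_freq`, `ref_allele`,
#'   `alt_allele` and `classification` columns.
#' @param config Optional overrides: `max_af` (default 0.01), `max_len`
#'   (default 50).
#' @return A list with `records` (kept rows) and `audit` (a `filter_audit`).
#' @export
filter_clinical <- function(records, config = list()) {
  check_classification_tokens(records)
  max_af <- config$max_af %||% 0.01
  max_len <- config$max_len %||% 50L
  net <- nchar(records$alt_allele) - nchar(records$ref_allele)
  rules <- list(
    gene_validity  = records$gene_validity %in% c("definitive", "strong", "moderate"),
    review_status  = records$review_stars >= 1L & !records$has_conflict,
    allele_freq    = is.na(records$allele_freq) | records$allele_freq <= max_af,
    length         = abs(net) <= max_len,
    classification = records$classification %in% c("P", "P/LP", "LP", "B", "B/LB", "LB"),
    in_frame       = net %% 3L == 0L & net != 0L
  )
  apply_rule_chain(records, rules)
}

#' Population (gnomAD-style) variant filter
#'
#' Same gene-tier, frequency, frame and length rules as [filter_clinical()],
#' plus the requirement that the variant passed all upstream variant-quality
#' filters (`qc_pass`). No clinical-classification rule applies.
#'
#' @inheritParams filter_clinical
#' @return A list with `records` and `audit`.
#' @export
filter_population <- function(records, config = list()) {
  max_af <- config$max_af %||% 0.01
  max_len <- config$max_len %||% 50L
  net <- nchar(records$alt_allele) - nchar(records$ref_allele)
  rules <- list(
    gene_validity = records$gene_validity %in% c("definitive", "strong", "moderate"),
    allele_freq   = is.na(records$allele_freq) | records$allele_freq <= max_af,
    in_frame      = net %% 3L == 0L & net != 0L,
    length        = abs(net) <= max_len,
    qc_pass       = isTRUE_vec(records$qc_pass)
  )
  apply_rule_chain(records, rules)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Proband genotype-quality filter
#'
#' Keeps calls with genotype quality >= 40, read depth >= 10, allele balance
#' >= 0.2 and net indel length <= 50 bp (all bounds inclusive). Records with
#' missing genotype fields are excluded by the corresponding rule and show up
#' in the audit; they never raise an error.
#'
#' @param records Variant data frame with `genotype_quality`, `depth`,
#'   `allele_balance`, `ref_allele`, `alt_allele` columns.
#' @param config Optional overrides: `min_gq` (40), `min_depth` (10),
#'   `min_ab` (0.2), `max_len` (50).
#' @return A list with `records` and `audit`.
#' @export
filter_genotypes <- function(records, config = list()) {
  min_gq <- config$min_gq %||% 40L
  min_depth <- config$min_depth %||% 10L
  min_ab <- config$min_ab %||% 0.2
  max_len <- config$max_len %||% 50L
  net <- nchar(records$alt_allele) - nchar(records$ref_allele)
  rules <- list(
    genotype_quality = !is.na(records$genotype_quality) & records$genotype_quality >= min_gq,
    depth            = !is.na(records$depth) & records$depth >= min_depth,
    allele_balance   = !is.na(records$allele_balance) & records$allele_balance >= min_ab,
    length           = abs(net) <= max_len
  )
  apply_rule_chain(records, rules)
}

#' Remove variants matching an exclusion key set
#'
#' Exact-key removal on (assembly, chrom, pos, ref_allele, alt_allele), used
#' for per-tool training-data exclusion and for removing clinical variants
#' from a population reference set before calibration. Keys are compared as
#' given; inputs are expected to be pre-normalised (left-aligned) upstream.
#'
#' @param records Variant data frame carrying the five key columns.
#' @param exclusion_keys Data frame with columns `assembly`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`.
#' @param allow_mixed_assemblies Set `TRUE` to permit records and keys drawn
#'   from different genome builds (matches are still exact, so cross-build
#'   keys simply never hit); otherwise mixing is an input error.
#' @return A list with `records` (remaining rows) and `removed` (count).
#' @export
exclude_overlap <- function(records, exclusion_keys, allow_mixed_assemblies = FALSE) {
  keycols <- c("assembly", "chrom", "pos", "ref_allele", "alt_allele")
  if (!all(keycols %in% names(records)) || !all(keycols %in% names(exclusion_keys)))
    abort_input("records and exclusion_keys must both carry the five key columns")
  if (!allow_mixed_assemblies &&
      nrow(exclusion_keys) > 0 && nrow(records) > 0 &&
      length(union(unique(records$assembly), unique(exclusion_keys$assembly))) > 1L)
    abort_input("records and exclusion keys mix genome assemblies; pass allow_mixed_assemblies = TRUE if intended")
  mk <- function(d) paste(d$assembly, d$chrom, d$pos, d$ref_allele, d$alt_allele,
                          sep = "\r")
  hit <- mk(records) %in% mk(exclusion_keys)
  kept <- records[!hit, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, removed = sum(hit))
}

#' Crop wild-type and variant protein sequences to a maximum window
#'
#' Sequence-model input windows: a sequence no longer than `max_len` is
#' returned unchanged; a longer one is cropped to exactly `max_len` residues
#' centred at `floor((var_start + var_end) / 2)` and shifted minimally to
#' stay within the sequence boundaries. An even window is split with one
#' extra residue on the left of the centre. The same procedure is applied
#' independently to the wild-type and variant sequences.
#'
#' @param wt_seq,var_seq Amino-acid strings.
#' @param var_start,var_end 1-based residue coordinates of the variant
#'   (inclusive); must fall inside the respective sequence.
#' @param max_len Window length, default 2046 (2048 model positions minus the
#'   start and end tokens).
#' @return A list with `wt`, `var` (cropped strings) and `wt_window`,
#'   `var_window` (1-based start/end of each window).
#' @export
crop_window <- function(wt_seq, var_seq, var_start, var_end, max_len = 2046L) {
  if (!is_count(var_start) || !is_count(var_end) || var_start > var_end)
    abort_input("need 1 <= var_start <= var_end")
  var_start <- as.integer(var_start); var_end <- as.integer(var_end)
  max_len <- as.integer(max_len)
  crop1 <- function(seqstr) {
    len <- nchar(seqstr)
    if (var_end > len)
      abort_input("variant coordinates fall outside the sequence")
    if (len <= max_len) return(list(seq = seqstr, window = c(1L, len)))
    center <- (var_start + var_end) %/% 2L
    start <- center - (max_len %/% 2L)          # left-biased split
    start <- max(1L, min(start, len - max_len + 1L))
    end <- start + max_len - 1L
    list(seq = substr(seqstr, start, end), window = c(start, end))
  }
  w <- crop1(wt_seq); v <- crop1(var_seq)
  list(wt = w$seq, var = v$seq, wt_window = w$window, var_window = v$window)
}
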
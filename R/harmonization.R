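# Allele harmonization: align exposure and outcome summary statistics to a
# shared effect allele, resolve strand flips and palindromic ambiguity, and
# orient every instrument to the exposure-increasing allele.

comp_allele <- function(a) unname(COMPLEMENT[a])

#' Harmonize exposure and outcome summary statistics
#'
#' Matches records on SNP id, aligns the outcome record to the exposure's
#' effect allele (flipping the sign of the outcome effect and complementing
#' its frequency when its effect allele is the exposure's other allele, and
#' resolving strand-complement label pairs), applies the palindromic policy,
#' and finally re-orients each instrument so the exposure effect is positive
#' (the exposure-increasing allele convention).  Every decision is recorded
#' in a per-SNP `flags` column; excluded records and their reasons are kept
#' in the `"exclusions"` attribute.
#'
#' Palindromic (A/T or G/C) variants cannot be aligned from labels alone:
#' `"drop_ambiguous"` excludes any whose exposure or outcome frequency falls
#' in the ambiguity window (default `[0.42, 0.58]`) and resolves the rest by
#' minor-allele matching; `"infer_by_eaf"` does the same (it is the default
#' policy); `"keep"` trusts the labels as reported.
#'
#' @param exposure,outcome summary-statistics data.frames (columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, ...).
#' @param palindromic_policy `"infer_by_eaf"`, `"drop_ambiguous"` or
#'   `"keep"`.
#' @param ambiguity_window frequency window within which a palindromic
#'   variant's orientation is considered unresolvable.
#' @return a data.frame of class `"harmonized_instruments"` with columns
#'   `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, `aligned_allele`, `other_allele`, `flags`.  `beta_exp > 0`
#'   for every retained instrument.
#' @examples
#' exp <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
#'                   eaf = 0.3, beta = 0.10, se = 0.02)
#' out <- data.frame(snp = "rs1", effect_allele = "G", other_allele = "A",
#'                   eaf = 0.7, beta = -0.05, se = 0.01)
#' harmonize(exp, out)  # beta_out becomes +0.05, aligned to allele A
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("infer_by_eaf", "drop_ambiguous",
                                             "keep"),
                      ambiguity_window = c(0.42, 0.58)) {
  palindromic_policy <- match.arg(palindromic_policy)
  excl <- data.frame(snp = character(), reason = character(),
                     stringsAsFactors = FALSE)
  only_exp <- setdiff(exposure$snp, outcome$snp)
  only_out <- setdiff(outcome$snp, exposure$snp)
  if (length(only_exp))
    excl <- rbind(excl, data.frame(snp = only_exp,
                                   reason = "absent from outcome study"))
  if (length(only_out))
    excl <- rbind(excl, data.frame(snp = only_out,
                                   reason = "absent from exposure study"))
  shared <- intersect(exposure$snp, outcome$snp)
  e <- exposure[match(shared, exposure$snp), ]
  o <- outcome[match(shared, outcome$snp), ]

  k <- length(shared)
  beta_out <- rep(NA_real_, k)
  eaf_out <- rep(NA_real_, k)
  flags <- vector("list", k)
  drop <- rep(FALSE, k)
  drop_reason <- rep(NA_character_, k)

  for (i in seq_len(k)) {
    ea_e <- e$effect_allele[i]; oa_e <- e$other_allele[i]
    ea_o <- o$effect_allele[i]; oa_o <- o$other_allele[i]
    fl <- character()
    palindromic <- identical(comp_allele(ea_e), oa_e)
    b <- o$beta[i]; fq <- o$eaf[i]

    if (!palindromic) {
      if (ea_o == ea_e && oa_o == oa_e) {
        # already aligned
      } else if (ea_o == oa_e && oa_o == ea_e) {
        b <- -b; fq <- 1 - fq; fl <- c(fl, "flipped")
      } else if (comp_allele(ea_o) == ea_e && comp_allele(oa_o) == oa_e) {
        fl <- c(fl, "strand_complement")
      } else if (comp_allele(ea_o) == oa_e && comp_allele(oa_o) == ea_e) {
        b <- -b; fq <- 1 - fq; fl <- c(fl, "strand_complement", "flipped")
      } else {
        drop[i] <- TRUE
        drop_reason[i] <- "incompatible allele pair"
        next
      }
    } else {
      same_pair <- setequal(c(ea_o, oa_o), c(ea_e, oa_e))
      if (!same_pair) {
        drop[i] <- TRUE
        drop_reason[i] <- "incompatible allele pair"
        next
      }
      if (palindromic_policy == "keep") {
        if (ea_o != ea_e) { b <- -b; fq <- 1 - fq; fl <- c(fl, "flipped") }
      } else {
        # align labels literally first, then let frequencies arbitrate
        if (ea_o != ea_e) { b <- -b; fq <- 1 - fq }
        ambiguous <- (e$eaf[i] >= ambiguity_window[1] &
                        e$eaf[i] <= ambiguity_window[2]) ||
                     (fq >= ambiguity_window[1] & fq <= ambiguity_window[2])
        if (ambiguous) {
          drop[i] <- TRUE
          drop_reason[i] <- "excluded_palindromic"
          next
        }
        if ((e$eaf[i] < 0.5) != (fq < 0.5)) {
          # minor alleles disagree: the reported labels referred to opposite
          # strands, so the literal alignment must be reversed
          b <- -b; fq <- 1 - fq; fl <- c(fl, "flipped")
        }
        fl <- c(fl, "palindromic_resolved")
      }
    }
    beta_out[i] <- b
    eaf_out[i] <- fq
    flags[[i]] <- fl
  }

  if (any(drop))
    excl <- rbind(excl, data.frame(snp = shared[drop],
                                   reason = drop_reason[drop]))
  keep <- !drop
  res <- data.frame(
    snp = shared[keep],
    beta_exp = e$beta[keep], se_exp = e$se[keep],
    beta_out = beta_out[keep], se_out = o$se[keep],
    eaf_exp = e$eaf[keep], eaf_out = eaf_out[keep],
    aligned_allele = e$effect_allele[keep],
    other_allele = e$other_allele[keep],
    stringsAsFactors = FALSE)
  flags <- flags[keep]

  # orient to the exposure-increasing allele
  neg <- res$beta_exp < 0
  if (any(neg)) {
    res$beta_exp[neg] <- -res$beta_exp[neg]
    res$beta_out[neg] <- -res$beta_out[neg]
    res$eaf_exp[neg] <- 1 - res$eaf_exp[neg]
    res$eaf_out[neg] <- 1 - res$eaf_out[neg]
    tmp <- res$aligned_allele[neg]
    res$aligned_allele[neg] <- res$other_allele[neg]
    res$other_allele[neg] <- tmp
    flags[neg] <- lapply(flags[neg], function(f) union(f, "oriented"))
  }
  res$flags <- vapply(flags, function(f)
    if (length(f)) paste(sort(f), collapse = ",") else "", character(1))
  attr(res, "exclusions") <- excl
  attr(res, "palindromic_policy") <- palindromic_policy
  class(res) <- c("harmonized_instruments", "data.frame")
  res
}

#' Rebuild exposure/outcome summary tables from harmonized instruments
#'
#' Inverse view of [harmonize()]: useful for round-trip checks and for
#' writing harmonized data back out in the summary-statistics dialect.
#'
#' @param x a `"harmonized_instruments"` data.frame.
#' @return a list with `exposure` and `outcome` summary-statistics tables.
#' @export
unharmonize <- function(x) {
  stopifnot(inherits(x, "harmonized_instruments"))
  mk <- function(beta, se, eaf) data.frame(
    snp = x$snp, effect_allele = x$aligned_allele,
    other_allele = x$other_allele, eaf = eaf, beta = beta, se = se,
    pval = 2 * stats::pnorm(-abs(beta / se)), n = NA_integer_,
    info = NA_real_, stringsAsFactors = FALSE)
  list(exposure = mk(x$beta_exp, x$se_exp, x$eaf_exp),
       outcome = mk(x$beta_out, x$se_out, x$eaf_out))
}
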
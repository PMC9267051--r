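#' Classify ribosome-inactivating protein (RIP) genes as type I or type II
#'
#' RIPs are typed by the absence (type I) or presence (type II) of a ricin
#' B-like lectin domain alongside the RIP domain; the lectin domain mediates
#' glycan binding and cell entry, so type-II RIPs are the more toxic class.
#' Domain presence means at least one annotation record for the signature on
#' the gene, regardless of coordinates or e-value.
#'
#' @param profiles A long domain-profile tibble with columns `gene_id`,
#'   `signature_id` (one row per gene-domain observation).
#' @param rip_sig Signature id of the RIP domain superfamily
#'   (default `"IPR036041"`).
#' @param lectin_sig Signature id of the ricin B-like lectin superfamily
#'   (default `"IPR035992"`).
#' @return A tibble with columns `gene_id`, `rip_type` (`"type_I"` or
#'   `"type_II"`); genes without the RIP domain are absent.
#' @examples
#' profiles <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g2"),
#'   signature_id = c("IPR036041", "IPR036041", "IPR035992")
#' )
#' classify_rip(profiles)
#' @export
classify_rip <- function(profiles, rip_sig = "IPR036041",
                         lectin_sig = "IPR035992") {
  profiles <- as_tibble(profiles)
  check_columns(profiles, c("gene_id", "signature_id"), "domain profiles")
  rip_genes <- unique(profiles$gene_id[profiles$signature_id == rip_sig])
  lectin_genes <- unique(profiles$gene_id[profiles$signature_id == lectin_sig])
  tibble(
    gene_id = rip_genes,
    rip_type = ifelse(rip_genes %in% lectin_genes, "type_II", "type_I")
  ) %>% arrange(.data$gene_id)
}

#' Two-domain Venn partition of gene profiles
#'
#' Counts genes carrying only the first signature, only the second, or both
#' (genes with neither are excluded), e.g. HATPase vs REC receiver domains
#' among histidine-kinase candidates.
#'
#' @inheritParams classify_rip
#' @param sig_a,sig_b The two signature ids (must differ).
#' @return A one-row tibble with columns `label_a`, `label_b`, `only_a`,
#'   `only_b`, `both`, `total`.
#' @export
venn_partition <- function(profiles, sig_a, sig_b) {
  if (identical(sig_a, sig_b)) abort("sig_a and sig_b must differ")
  profiles <- as_tibble(profiles)
  check_columns(profiles, c("gene_id", "signature_id"), "domain profiles")
  a <- unique(profiles$gene_id[profiles$signature_id == sig_a])
  b <- unique(profiles$gene_id[profiles$signature_id == sig_b])
  both <- length(intersect(a, b))
  tibble(
    label_a = sig_a, label_b = sig_b,
    only_a = length(a) - both,
    only_b = length(b) - both,
    both = both,
    total = length(union(a, b))
  )
}
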
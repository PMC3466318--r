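#' Conserved-domain catalog for the LuxR regulator family
#'
#' Maps the CDD/Pfam accessions used in the LuxR-family census to the short
#' labels that make up architecture strings. The anchor domain is the
#' C-terminal helix-turn-helix LuxR_C_like domain (cd06170; the Pfam GerE
#' model PF00196 describes the same region). The remaining entries are the
#' signal-transduction domains observed fused to it: the CheY-like receiver
#' (REC), PAS, metal-dependent phosphohydrolase (HDc), AAA ATPase, cyclase
#' homology (CHD), forkhead-associated (FHA), protein-kinase catalytic (PKc),
#' tetratricopeptide repeat (TPR) and cold-shock (CSP_CDS) domains.
#'
#' @return A data frame with columns `accession`, `label` and `description`.
#' @export
#' @examples
#' domain_catalog()
domain_catalog <- function() {
  data.frame(
    accession = c("cd06170", "PF00196", "cd00156", "cd00130", "cd00077",
                  "cd00009", "cd07302", "cd00060", "cd00180", "cd00189",
                  "cd04458"),
    label = c("LuxR", "LuxR", "REC", "PAS", "HDc", "AAA", "CHD", "FHA",
              "PKc", "TPR", "CSP_CDS"),
    description = c(
      "LuxR_C_like C-terminal HTH DNA-binding domain",
      "GerE HTH domain (Pfam model of the LuxR C-terminus)",
      "CheY-like phosphoacceptor receiver domain",
      "Per/Arnt/Sim sensor domain",
      "Metal-dependent phosphohydrolase domain",
      "ATPase associated with diverse cellular activities",
      "Cyclase homology domain",
      "Forkhead-associated domain",
      "Protein kinase catalytic domain",
      "Tetratricopeptide repeat domain",
      "Cold-shock protein with S1-like cold-shock domain"),
    stringsAsFactors = FALSE
  )
}

#' Default anchor accession for the LuxR-family census
#'
#' The curated CDD domain corresponding to the LuxR C-terminal HTH.
#' @return The string `"cd06170"`.
#' @export
anchor_accession <- function() "cd06170"

# Resolve accessions to labels through a catalog; unknown accessions keep the
# accession itself as label (so no specific hit is silently dropped) or raise,
# depending on `unknown`.
catalog_label <- function(acc, catalog = domain_catalog(),
                          unknown = c("accession", "error")) {
  unknown <- match.arg(unknown)
  idx <- match(acc, catalog$accession)
  lab <- catalog$label[idx]
  miss <- is.na(idx)
  if (any(miss)) {
    if (unknown == "error") {
      stop("accession(s) absent from catalog: ",
           paste(unique(acc[miss]), collapse = ", "), call. = FALSE)
    }
    warning("accession(s) absent from catalog kept as labels: ",
            paste(unique(acc[miss]), collapse = ", "), call. = FALSE)
    lab[miss] <- acc[miss]
  }
  lab
}
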
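# Quantitative estimate of drug-likeness (QED): the weighted geometric mean
# of eight desirability-transformed properties (MW, ALOGP, HBA, HBD, PSA,
# ROTB, AROM, ALERTS). Desirability functions are asymmetric double
# sigmoids (ADS) with the published parameterization; weights are the
# published mean-weight set.

QED_ADS <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
             E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,
             E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,
             E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 1e-09,
             E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,
             E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB   = c(A = 0.01, B = 272.4121427, C = 2.55837997, D = 1.565547684,
             E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM   = c(A = 3.21778897, B = 957.7374108, C = 2.274627939, D = 1e-09,
             E = 1.317690384, F = 0.375760881, DMAX = 312.337261),
  ALERTS = c(A = 0.01, B = 1199.094025, C = -0.09002883, D = 1e-09,
             E = 0.185904477, F = 0.875193782, DMAX = 417.725314)
)

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# Hydrogen-bond acceptor/donor definitions of the QED parameterization.
QED_ACCEPTOR_SMARTS <- c(
  "[oH0;X2]", "[OH1;X2;v2]", "[OH0;X2;v2]", "[OH0;X1;v2]", "[O-;X1]",
  "[SH0;X2;v2]", "[SH0;X1;v2]", "[S-;X1]", "[nH0;X2]", "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]"
)
QED_DONOR_SMARTS <-
  "[$([N;!H0;v3]),$([N;!H0;+1;v4]),$([O,S;H1;+0]),$([n;H1;+0])]"
ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

qed_ads <- function(x, p) {
  v <- p["A"] +
    p["B"] / (1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])) *
      (1 - 1 / (1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])))
  pmin(pmax(v / p["DMAX"], 1e-6), 1)
}

# The eight QED input properties for a vector of curated SMILES.
qed_properties <- function(smiles) {
  props <- ob_properties(smiles)
  sdf <- as_sdfset(smiles)
  hba <- rowSums(vapply(QED_ACCEPTOR_SMARTS,
                        function(p) smarts_count(sdf, p),
                        integer(length(smiles))))
  hbd <- smarts_count(sdf, QED_DONOR_SMARTS)
  rotb <- smarts_count(sdf, ROTB_SMARTS)
  arom <- vapply(seq_along(smiles),
                 function(i) ring_info(sdf[[i]])$n_aromatic, integer(1))
  alerts <- qed_alert_count(sdf, length(smiles))
  tibble::tibble(MW = props$MW, ALOGP = props$logP, HBA = as.numeric(hba),
                 HBD = as.numeric(hbd), PSA = props$TPSA,
                 ROTB = as.numeric(rotb), AROM = as.numeric(arom),
                 ALERTS = as.numeric(alerts))
}

qed_alert_count <- function(sdf, n) {
  hits <- matrix(0L, nrow = n, ncol = nrow(qed_alert_patterns))
  for (j in seq_len(nrow(qed_alert_patterns))) {
    cnt <- tryCatch(smarts_count(sdf, qed_alert_patterns$smarts[j]),
                    error = function(e) rep(0L, n))
    hits[, j] <- as.integer(cnt >= qed_alert_patterns$min_count[j])
  }
  rowSums(hits)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Computes QED, the weighted geometric mean of eight
#' desirability-transformed molecular properties (molecular weight, logP,
#' acceptor and donor counts, polar surface area, rotatable bonds, aromatic
#' rings, structural alerts), on a 0 (worst) to 1 (best) scale. Compounds
#' with `qed >= 0.67` are conventionally considered attractive.
#'
#' @param smiles Character vector of curated SMILES.
#' @return A tibble with columns `smiles`, the eight property values,
#'   `qed`, and logical `attractive` (`qed >= 0.67`).
#' @export
qed_score <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  props <- qed_properties(smiles)
  d <- vapply(names(QED_ADS), function(nm) qed_ads(props[[nm]], QED_ADS[[nm]]),
              numeric(length(smiles)))
  if (length(smiles) == 1L) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(QED_ADS)))
  w <- QED_WEIGHTS[colnames(d)]
  q <- as.vector(exp(log(d) %*% w / sum(w)))
  tibble::tibble(smiles = smiles, props, qed = q, attractive = q >= 0.67)
}
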
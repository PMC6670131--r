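# Species ordering is frozen: it follows the order in which the governing
# kinetic equations are written, and is used for all file I/O.
.SPECIES <- c(
  "Hotair", "WIF1", "Wnt", "WIF1_Wnt", "LRP56", "Fzl", "Fzl_LRP56",
  "Wnt_Fzl_LRP56", "Axin_LRP56", "Axin", "Dsh_i", "Dsh_a",
  "APC_Axin_GSK3", "APCp_Axinp_GSK3", "GSK3", "APC_Axin", "APC",
  "Bcat_APCp_Axinp_GSK3", "Bcatp_APCp_Axinp_GSK3", "Bcatp", "Bcat",
  "TCF", "Bcat_TCF", "Bcat_APC", "MMP13")

# Starred species are phosphorylated forms (APCp = APC*, Bcatp =
# phospho-beta-catenin). Printed-style names are accepted as aliases.
.SPECIES_ALIASES <- c(
  "HOTAIR" = "Hotair", "WIF-1" = "WIF1", "WIF_1" = "WIF1",
  "WIF-1.Wnt" = "WIF1_Wnt", "WIF_1.Wnt" = "WIF1_Wnt",
  "LRP5/6" = "LRP56", "Fzl.LRP5/6" = "Fzl_LRP56",
  "Wnt.Fzl.LRP5/6" = "Wnt_Fzl_LRP56", "Axin.LRP5/6" = "Axin_LRP56",
  "Dsh" = "Dsh_i", "Dshi" = "Dsh_i", "Dsha" = "Dsh_a",
  "APC.Axin.GSK3" = "APC_Axin_GSK3",
  "APC*.Axin*.GSK3" = "APCp_Axinp_GSK3",
  "APC.Axin" = "APC_Axin",
  "beta-catenin.APC*.Axin*.GSK3" = "Bcat_APCp_Axinp_GSK3",
  "beta-catenin*.APC*.Axin*.GSK3" = "Bcatp_APCp_Axinp_GSK3",
  "beta-catenin*" = "Bcatp", "beta-catenin" = "Bcat",
  "beta_catenin" = "Bcat", "b-catenin" = "Bcat",
  "beta-catenin.TCF" = "Bcat_TCF", "beta-catenin.APC" = "Bcat_APC",
  "MMP-13" = "MMP13")

.resolveSpeciesNames <- function(nm) {
  hit <- match(nm, names(.SPECIES_ALIASES))
  nm[!is.na(hit)] <- .SPECIES_ALIASES[hit[!is.na(hit)]]
  bad <- setdiff(nm, .SPECIES)
  if (length(bad))
    stop("unknown species name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nm
}

#' Names of the 25 model species
#'
#' Fixed, documented ordering (the order the governing equations are
#' written in). `p` suffixes denote phosphorylated (starred) forms;
#' underscores join complex members. Printed-style names such as
#' `"LRP5/6"` or `"beta-catenin"` are accepted as aliases wherever species
#' names are taken as input.
#'
#' @return character vector of length 25.
#' @export
speciesNames <- function() .SPECIES

#' Default initial state
#'
#' Concentrations in nM at t = 0. Free Wnt, Fzl, WIF-1, LRP5/6 start at
#' 10 nM, inactive Dsh at 100, APC at 100, TCF at 15 and GSK3 at 50; every
#' other species (HOTAIR, Axin, beta-catenin and all complexes) starts at 0,
#' reflecting an unbound/unproduced pool that the synthesis reactions then
#' populate.
#'
#' @param overrides named numeric vector or list of species concentrations
#'   to override (aliases accepted); unknown names are rejected.
#' @return named numeric vector of length 25 (nM).
#' @examples
#' s <- initialState()
#' s[["GSK3"]]
#' initialState(c(Wnt = 0))[["Wnt"]]
#' @export
initialState <- function(overrides = NULL) {
  s <- stats::setNames(numeric(25), .SPECIES)
  s[c("Wnt", "Fzl", "WIF1", "LRP56")] <- 10
  s["Dsh_i"] <- 100
  s["APC"] <- 100
  s["TCF"] <- 15
  s["GSK3"] <- 50
  if (length(overrides)) {
    ov <- unlist(overrides)
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("initial-state overrides must be named", call. = FALSE)
    nm <- .resolveSpeciesNames(names(ov))
    s[nm] <- as.numeric(ov)
  }
  if (any(s < 0))
    stop("initial concentrations must be non-negative", call. = FALSE)
  s
}

# Reaction catalogue: 37 reactions (reversible steps split into forward "f"
# and reverse "r"), each tied to exactly one rate constant. `reactants` /
# `products` list only converted species; catalytic effectors enter the rate
# law but not the stoichiometry.
.REACTIONS <- list(
  list(id = "r1",  param = "k1",   kind = "zeroth-order",
       reactants = character(), products = "Hotair",
       desc = "HOTAIR synthesis"),
  list(id = "r2",  param = "k2",   kind = "first-order",
       reactants = "Hotair", products = character(),
       desc = "HOTAIR degradation"),
  list(id = "r3",  param = "V3",   kind = "Hill-repression",
       reactants = character(), products = "WIF1",
       desc = "WIF-1 synthesis, Hill-repressed by HOTAIR"),
  list(id = "r4f", param = "k4",   kind = "second-order",
       reactants = c("WIF1", "Wnt"), products = "WIF1_Wnt",
       desc = "WIF-1 + Wnt binding"),
  list(id = "r4r", param = "km4",  kind = "first-order",
       reactants = "WIF1_Wnt", products = c("WIF1", "Wnt"),
       desc = "WIF-1.Wnt dissociation"),
  list(id = "r5f", param = "k5",   kind = "second-order",
       reactants = c("LRP56", "Fzl"), products = "Fzl_LRP56",
       desc = "LRP5/6 + Fzl binding"),
  list(id = "r5r", param = "km5",  kind = "first-order",
       reactants = "Fzl_LRP56", products = c("LRP56", "Fzl"),
       desc = "Fzl.LRP5/6 dissociation"),
  list(id = "r6f", param = "k6",   kind = "second-order",
       reactants = c("Wnt", "Fzl_LRP56"), products = "Wnt_Fzl_LRP56",
       desc = "Wnt + Fzl.LRP5/6 binding"),
  list(id = "r6r", param = "km6",  kind = "first-order",
       reactants = "Wnt_Fzl_LRP56", products = c("Wnt", "Fzl_LRP56"),
       desc = "Wnt.Fzl.LRP5/6 dissociation"),
  list(id = "r7f", param = "k7",   kind = "second-order",
       reactants = c("Axin", "LRP56"), products = "Axin_LRP56",
       desc = "Axin + LRP5/6 binding"),
  list(id = "r7r", param = "km7",  kind = "first-order",
       reactants = "Axin_LRP56", products = c("Axin", "LRP56"),
       desc = "Axin.LRP5/6 dissociation"),
  list(id = "r8",  param = "k8",   kind = "Michaelis-type",
       reactants = "Dsh_i", products = "Dsh_a",
       desc = "Dsh activation by the active receptor complex"),
  list(id = "r9",  param = "k9",   kind = "first-order",
       reactants = "Dsh_a", products = "Dsh_i",
       desc = "Dsh deactivation"),
  list(id = "r10", param = "k10",  kind = "second-order",
       reactants = "APC_Axin_GSK3", products = c("APC_Axin", "GSK3"),
       desc = "Dsh_a-driven GSK3 release from the destruction complex"),
  list(id = "r11f", param = "k11",  kind = "second-order",
       reactants = c("GSK3", "APC_Axin"), products = "APC_Axin_GSK3",
       desc = "GSK3 + APC.Axin binding"),
  list(id = "r11r", param = "km11", kind = "first-order",
       reactants = "APC_Axin_GSK3", products = c("GSK3", "APC_Axin"),
       desc = "GSK3 dissociation from APC.Axin.GSK3"),
  list(id = "r12f", param = "k12",  kind = "first-order",
       reactants = "APC_Axin_GSK3", products = "APCp_Axinp_GSK3",
       desc = "phosphorylation of APC and Axin"),
  list(id = "r12r", param = "km12", kind = "first-order",
       reactants = "APCp_Axinp_GSK3", products = "APC_Axin_GSK3",
       desc = "dephosphorylation of APC* and Axin*"),
  list(id = "r13f", param = "k13",  kind = "second-order",
       reactants = c("APC", "Axin"), products = "APC_Axin",
       desc = "APC + Axin binding"),
  list(id = "r13r", param = "km13", kind = "first-order",
       reactants = "APC_Axin", products = c("APC", "Axin"),
       desc = "APC.Axin dissociation"),
  list(id = "r14f", param = "k14",  kind = "second-order",
       reactants = c("Bcat", "APCp_Axinp_GSK3"),
       products = "Bcat_APCp_Axinp_GSK3",
       desc = "beta-catenin binding to the phosphorylated complex"),
  list(id = "r14r", param = "km14", kind = "first-order",
       reactants = "Bcat_APCp_Axinp_GSK3",
       products = c("Bcat", "APCp_Axinp_GSK3"),
       desc = "beta-catenin dissociation from the complex"),
  list(id = "r15", param = "k15",  kind = "first-order",
       reactants = "Bcat_APCp_Axinp_GSK3",
       products = "Bcatp_APCp_Axinp_GSK3",
       desc = "beta-catenin phosphorylation"),
  list(id = "r16", param = "k16",  kind = "first-order",
       reactants = "Bcatp_APCp_Axinp_GSK3",
       products = c("Bcatp", "APCp_Axinp_GSK3"),
       desc = "release of phospho-beta-catenin"),
  list(id = "r17", param = "k17",  kind = "first-order",
       reactants = "Bcatp", products = character(),
       desc = "phospho-beta-catenin degradation"),
  list(id = "r18", param = "k18",  kind = "zeroth-order",
       reactants = character(), products = "Axin",
       desc = "basal Axin synthesis"),
  list(id = "r19", param = "k19",  kind = "first-order",
       reactants = "Axin", products = character(),
       desc = "Axin degradation"),
  list(id = "r20f", param = "k20",  kind = "second-order",
       reactants = c("APC", "Bcat"), products = "Bcat_APC",
       desc = "APC + beta-catenin binding"),
  list(id = "r20r", param = "km20", kind = "first-order",
       reactants = "Bcat_APC", products = c("APC", "Bcat"),
       desc = "beta-catenin.APC dissociation"),
  list(id = "r21", param = "k21",  kind = "zeroth-order",
       reactants = character(), products = "Bcat",
       desc = "beta-catenin synthesis"),
  list(id = "r22", param = "k22",  kind = "first-order",
       reactants = "Bcat", products = character(),
       desc = "beta-catenin degradation"),
  list(id = "r23f", param = "k23",  kind = "second-order",
       reactants = c("Bcat", "TCF"), products = "Bcat_TCF",
       desc = "beta-catenin + TCF binding"),
  list(id = "r23r", param = "km23", kind = "first-order",
       reactants = "Bcat_TCF", products = c("Bcat", "TCF"),
       desc = "beta-catenin.TCF dissociation"),
  list(id = "r24", param = "k24",  kind = "first-order",
       reactants = character(), products = "Axin",
       desc = "Axin synthesis induced by beta-catenin/TCF (negative feedback)"),
  list(id = "r25", param = "k25",  kind = "zeroth-order",
       reactants = character(), products = "MMP13",
       desc = "basal MMP-13 synthesis"),
  list(id = "r26", param = "k26",  kind = "first-order",
       reactants = "MMP13", products = character(),
       desc = "MMP-13 degradation"),
  list(id = "r27", param = "V27",  kind = "Hill-activation",
       reactants = character(), products = "MMP13",
       desc = "beta-catenin.TCF-driven MMP-13 synthesis"))

#' Reaction ids of the 37-reaction network
#'
#' Reversible steps are split into a forward (`f`) and reverse (`r`)
#' reaction, each carrying its own rate constant.
#'
#' @return character vector of length 37.
#' @export
reactionIds <- function() vapply(.REACTIONS, `[[`, "", "id")

#' Reaction catalogue
#'
#' One row per reaction: id, rate-law kind, the rate constant it uses and a
#' description. The `mmp13Hill` switch selects the regulatory form of the
#' MMP-13 synthesis step (see [evaluateFluxes()]).
#'
#' @param mmp13Hill `"activating"` (default) or `"printed"` (repressive).
#' @return data.frame with 37 rows.
#' @export
reactionTable <- function(mmp13Hill = c("activating", "printed")) {
  mmp13Hill <- match.arg(mmp13Hill)
  out <- data.frame(
    id = vapply(.REACTIONS, `[[`, "", "id"),
    kind = vapply(.REACTIONS, `[[`, "", "kind"),
    parameter = vapply(.REACTIONS, `[[`, "", "param"),
    description = vapply(.REACTIONS, `[[`, "", "desc"),
    stringsAsFactors = FALSE)
  if (mmp13Hill == "printed")
    out$kind[out$id == "r27"] <- "Hill-repression"
  out
}

#' Stoichiometry matrix of the network
#'
#' 25 species x 37 reactions; entry (i, j) is the net number of molecules of
#' species i produced by one firing of reaction j. Catalytic effectors
#' (Dsh_a in GSK3 release, the active receptor complex in Dsh activation,
#' beta-catenin and beta-catenin.TCF in induced Axin synthesis) are not
#' consumed and so do not appear.
#'
#' @return integer matrix with dimnames (species, reaction ids).
#' @export
stoichiometryMatrix <- function() {
  N <- matrix(0L, length(.SPECIES), length(.REACTIONS),
              dimnames = list(.SPECIES, reactionIds()))
  for (j in seq_along(.REACTIONS)) {
    r <- .REACTIONS[[j]]
    for (s in r$reactants) N[s, j] <- N[s, j] - 1L
    for (s in r$products)  N[s, j] <- N[s, j] + 1L
  }
  N
}

#' Conserved moieties of the network
#'
#' Seven totals are invariant under every reaction: total Wnt, Fzl, LRP5/6,
#' Dsh, GSK3, APC and TCF (each the sum of the free species and all
#' complexes containing it).
#'
#' @return named list of species-name vectors.
#' @export
conservedMoieties <- function() list(
  Wnt   = c("Wnt", "WIF1_Wnt", "Wnt_Fzl_LRP56"),
  Fzl   = c("Fzl", "Fzl_LRP56", "Wnt_Fzl_LRP56"),
  LRP56 = c("LRP56", "Fzl_LRP56", "Wnt_Fzl_LRP56", "Axin_LRP56"),
  Dsh   = c("Dsh_i", "Dsh_a"),
  GSK3  = c("GSK3", "APC_Axin_GSK3", "APCp_Axinp_GSK3",
            "Bcat_APCp_Axinp_GSK3", "Bcatp_APCp_Axinp_GSK3"),
  APC   = c("APC", "APC_Axin", "APC_Axin_GSK3", "APCp_Axinp_GSK3",
            "Bcat_APCp_Axinp_GSK3", "Bcatp_APCp_Axinp_GSK3", "Bcat_APC"),
  TCF   = c("TCF", "Bcat_TCF"))

#' Conserved-moiety totals of a state
#'
#' @param state named numeric state vector (length 25) or a state matrix
#'   with species columns.
#' @return named numeric vector (or matrix) of the 7 moiety totals, nM.
#' @examples
#' conservedTotals(initialState())
#' @export
conservedTotals <- function(state) {
  mo <- conservedMoieties()
  if (is.matrix(state)) {
    out <- sapply(mo, function(m) rowSums(state[, m, drop = FALSE]))
    if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(mo)))
    out
  } else {
    vapply(mo, function(m) sum(state[m]), numeric(1))
  }
}

.checkState <- function(state) {
  if (is.matrix(state)) {
    if (ncol(state) != 25L) stop("state matrix must have 25 columns",
                                 call. = FALSE)
    if (is.null(colnames(state))) colnames(state) <- .SPECIES
    if (any(state < 0)) stop("negative concentration in state",
                             call. = FALSE)
    state
  } else {
    if (length(state) != 25L) stop("state must have length 25",
                                   call. = FALSE)
    if (is.null(names(state))) names(state) <- .SPECIES
    if (any(state < 0)) stop("negative concentration in state",
                             call. = FALSE)
    matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  }
}

#' Evaluate the 37 reaction fluxes
#'
#' Mass-action rate laws, a Michaelis-type law for Dsh activation
#' (k8 [Wnt.Fzl.LRP5/6] [Dsh_i] / (K8 + [Dsh_i])), a Hill-repression law for
#' WIF-1 synthesis (V3 K3^m3 / (K3^m3 + [HOTAIR]^m3)) and a Hill law for the
#' regulated MMP-13 synthesis step. The default MMP-13 form is activating,
#' V27 [beta-catenin.TCF]^m27 / (K27^m27 + [beta-catenin.TCF]^m27), which is
#' consistent with the step's description and with MMP-13 falling when Axin
#' synthesis rises; `mmp13Hill = "printed"` selects the repressive
#' alternative V27 K27^m27 / (K27^m27 + [beta-catenin.TCF]^m27).
#'
#' @param state named numeric vector (length 25, nM), or a state matrix with
#'   one row per time point; negative entries are rejected.
#' @param params a [WntParameterSet-class].
#' @param mmp13Hill `"activating"` (default) or `"printed"`.
#' @return named numeric vector of 37 fluxes (nM/min), or a matrix with one
#'   row per state row.
#' @examples
#' f <- evaluateFluxes(initialState(), defaultParameters())
#' f[["r3"]]  # WIF-1 synthesis flux
#' @export
evaluateFluxes <- function(state, params,
                           mmp13Hill = c("activating", "printed")) {
  mmp13Hill <- match.arg(mmp13Hill)
  single <- !is.matrix(state)
  x <- .checkState(state)
  p <- paramValues(params)
  n <- nrow(x)
  g <- function(s) x[, s]
  hill3 <- p["V3"] * p["K3"]^p["m3"] /
    (p["K3"]^p["m3"] + g("Hotair")^p["m3"])
  bt <- g("Bcat_TCF")
  hill27 <- if (mmp13Hill == "activating") {
    p["V27"] * bt^p["m27"] / (p["K27"]^p["m27"] + bt^p["m27"])
  } else {
    p["V27"] * p["K27"]^p["m27"] / (p["K27"]^p["m27"] + bt^p["m27"])
  }
  F <- cbind(
    r1 = rep(p["k1"], n),
    r2 = p["k2"] * g("Hotair"),
    r3 = hill3,
    r4f = p["k4"] * g("WIF1") * g("Wnt"),
    r4r = p["km4"] * g("WIF1_Wnt"),
    r5f = p["k5"] * g("LRP56") * g("Fzl"),
    r5r = p["km5"] * g("Fzl_LRP56"),
    r6f = p["k6"] * g("Wnt") * g("Fzl_LRP56"),
    r6r = p["km6"] * g("Wnt_Fzl_LRP56"),
    r7f = p["k7"] * g("Axin") * g("LRP56"),
    r7r = p["km7"] * g("Axin_LRP56"),
    r8 = p["k8"] * g("Wnt_Fzl_LRP56") * g("Dsh_i") / (p["K8"] + g("Dsh_i")),
    r9 = p["k9"] * g("Dsh_a"),
    r10 = p["k10"] * g("APC_Axin_GSK3") * g("Dsh_a"),
    r11f = p["k11"] * g("GSK3") * g("APC_Axin"),
    r11r = p["km11"] * g("APC_Axin_GSK3"),
    r12f = p["k12"] * g("APC_Axin_GSK3"),
    r12r = p["km12"] * g("APCp_Axinp_GSK3"),
    r13f = p["k13"] * g("APC") * g("Axin"),
    r13r = p["km13"] * g("APC_Axin"),
    r14f = p["k14"] * g("APCp_Axinp_GSK3") * g("Bcat"),
    r14r = p["km14"] * g("Bcat_APCp_Axinp_GSK3"),
    r15 = p["k15"] * g("Bcat_APCp_Axinp_GSK3"),
    r16 = p["k16"] * g("Bcatp_APCp_Axinp_GSK3"),
    r17 = p["k17"] * g("Bcatp"),
    r18 = rep(p["k18"], n),
    r19 = p["k19"] * g("Axin"),
    r20f = p["k20"] * g("APC") * g("Bcat"),
    r20r = p["km20"] * g("Bcat_APC"),
    r21 = rep(p["k21"], n),
    r22 = p["k22"] * g("Bcat"),
    r23f = p["k23"] * g("Bcat") * g("TCF"),
    r23r = p["km23"] * g("Bcat_TCF"),
    r24 = p["k24"] * (g("Bcat_TCF") + g("Bcat")),
    r25 = rep(p["k25"], n),
    r26 = p["k26"] * g("MMP13"),
    r27 = hill27)
  if (single) F[1, ] else F
}

# Direct transcription of the 25 governing equations; kept deliberately
# independent of the stoichiometry x flux path as an internal cross-check.
.rhsDirect <- function(state, params,
                       mmp13Hill = c("activating", "printed")) {
  mmp13Hill <- match.arg(mmp13Hill)
  p <- as.list(paramValues(params))
  y <- as.list(state)
  names(y) <- .SPECIES
  with(c(p, y), {
    hill3 <- V3 * K3^m3 / (K3^m3 + Hotair^m3)
    dshAct <- k8 * Wnt_Fzl_LRP56 * Dsh_i / (K8 + Dsh_i)
    hill27 <- if (mmp13Hill == "activating")
      V27 * Bcat_TCF^m27 / (K27^m27 + Bcat_TCF^m27)
    else
      V27 * K27^m27 / (K27^m27 + Bcat_TCF^m27)
    c(
      Hotair = k1 - k2 * Hotair,
      WIF1 = hill3 + km4 * WIF1_Wnt - k4 * WIF1 * Wnt,
      Wnt = km4 * WIF1_Wnt - k4 * WIF1 * Wnt +
        km6 * Wnt_Fzl_LRP56 - k6 * Wnt * Fzl_LRP56,
      WIF1_Wnt = k4 * WIF1 * Wnt - km4 * WIF1_Wnt,
      LRP56 = km5 * Fzl_LRP56 - k5 * LRP56 * Fzl +
        km7 * Axin_LRP56 - k7 * Axin * LRP56,
      Fzl = km5 * Fzl_LRP56 - k5 * Fzl * LRP56,
      Fzl_LRP56 = k5 * Fzl * LRP56 - km5 * Fzl_LRP56 +
        km6 * Wnt_Fzl_LRP56 - k6 * Wnt * Fzl_LRP56,
      Wnt_Fzl_LRP56 = k6 * Wnt * Fzl_LRP56 - km6 * Wnt_Fzl_LRP56,
      Axin_LRP56 = k7 * Axin * LRP56 - km7 * Axin_LRP56,
      Axin = k18 - k19 * Axin + km13 * APC_Axin - k13 * APC * Axin +
        km7 * Axin_LRP56 - k7 * Axin * LRP56 +
        k24 * (Bcat_TCF + Bcat),
      Dsh_i = k9 * Dsh_a - dshAct,
      Dsh_a = dshAct - k9 * Dsh_a,
      APC_Axin_GSK3 = -k10 * APC_Axin_GSK3 * Dsh_a -
        km11 * APC_Axin_GSK3 - k12 * APC_Axin_GSK3 +
        km12 * APCp_Axinp_GSK3 + k11 * GSK3 * APC_Axin,
      APCp_Axinp_GSK3 = k16 * Bcatp_APCp_Axinp_GSK3 +
        k12 * APC_Axin_GSK3 - km12 * APCp_Axinp_GSK3 +
        km14 * Bcat_APCp_Axinp_GSK3 - k14 * APCp_Axinp_GSK3 * Bcat,
      GSK3 = k10 * APC_Axin_GSK3 * Dsh_a + km11 * APC_Axin_GSK3 -
        k11 * GSK3 * APC_Axin,
      APC_Axin = k10 * APC_Axin_GSK3 * Dsh_a + km11 * APC_Axin_GSK3 -
        k11 * GSK3 * APC_Axin - km13 * APC_Axin + k13 * APC * Axin,
      APC = -k20 * APC * Bcat + km20 * Bcat_APC +
        km13 * APC_Axin - k13 * APC * Axin,
      Bcat_APCp_Axinp_GSK3 = -k15 * Bcat_APCp_Axinp_GSK3 -
        km14 * Bcat_APCp_Axinp_GSK3 + k14 * APCp_Axinp_GSK3 * Bcat,
      Bcatp_APCp_Axinp_GSK3 = k15 * Bcat_APCp_Axinp_GSK3 -
        k16 * Bcatp_APCp_Axinp_GSK3,
      Bcatp = k16 * Bcatp_APCp_Axinp_GSK3 - k17 * Bcatp,
      Bcat = k21 - k22 * Bcat - k23 * Bcat * TCF + km23 * Bcat_TCF -
        k20 * Bcat * APC + km20 * Bcat_APC +
        km14 * Bcat_APCp_Axinp_GSK3 - k14 * APCp_Axinp_GSK3 * Bcat,
      TCF = -k23 * Bcat * TCF + km23 * Bcat_TCF,
      Bcat_TCF = k23 * Bcat * TCF - km23 * Bcat_TCF,
      Bcat_APC = k20 * APC * Bcat - km20 * Bcat_APC,
      MMP13 = k25 + hill27 - k26 * MMP13)
  })
}

#' Evaluate the time derivatives of the 25 species
#'
#' The default path multiplies the stoichiometry matrix by the flux vector;
#' `method = "direct"` instead evaluates a hand-transcribed copy of the 25
#' governing equations, kept in the package as an internal cross-check
#' oracle. Both paths agree to numerical round-off.
#'
#' @inheritParams evaluateFluxes
#' @param method `"stoichiometry"` (default) or `"direct"`.
#' @return named numeric vector of 25 derivatives (nM/min).
#' @examples
#' d <- evaluateRHS(initialState(), defaultParameters())
#' d[["Hotair"]]  # k1 at the default initial state
#' @export
evaluateRHS <- function(state, params,
                        method = c("stoichiometry", "direct"),
                        mmp13Hill = c("activating", "printed")) {
  method <- match.arg(method)
  mmp13Hill <- match.arg(mmp13Hill)
  if (method == "direct")
    return(.rhsDirect(state, params, mmp13Hill))
  f <- evaluateFluxes(state, params, mmp13Hill)
  drop(stoichiometryMatrix() %*% f)
}
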
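# Programmatic constructors for the three case-study models.  These are
# the package's only data source; each returns the network plus its
# canonical properties.

#' Birth-death fixture
#'
#' One species X bounded at `bound`: constant production at rate k1
#' (uncertain by default) and first-order degradation at rate k2 * X.
#' Canonical property: the probability that the population lies between
#' 15 and 20 at time 1000.
#'
#' @param bound Population bound (default 40, giving 41 states).
#' @param k1_interval Production-rate interval.
#' @param k2 Degradation rate constant.
#' @param x0 Initial population.
#' @return A `stochrob_fixture`: `network`, `properties` (named formula
#'   list), `name`.
#' @export
birth_death <- function(bound = 40, k1_interval = c(0.05, 0.1), k2 = 0.005,
                        x0 = 25) {
  stopifnot(bound >= 0)
  x0 <- min(x0, bound)
  net <- reaction_network(
    species = list(species("X", bound)),
    reactions = list(
      reaction(products = c(X = 1), rate = mass_action("k1"),
               name = "production"),
      reaction(reactants = c(X = 1), rate = mass_action("k2"),
               name = "degradation")),
    constants = list(k1 = k1_interval, k2 = k2),
    initial_states = list(c(X = x0)),
    labels = c(mid = "X >= 15 & X <= 20"))
  props <- list(
    mid_at_1000 = prob_op(path_until(csl_atomic("true"),
                                     csl_atomic("X >= 15 & X <= 20"),
                                     1000, 1000)))
  structure(list(name = "birth_death", network = net, properties = props),
            class = "stochrob_fixture")
}

#' Bistable gene-regulation fixture (mammalian cell-cycle switch)
#'
#' Two transcription factors: the tumour-suppressor protein A and the
#' positively self-regulating factor B, each bounded at 10 molecules,
#' with one DNA copy per gene (conserved across free and bound forms).
#' Each gene carries a single operator site that reversibly binds either
#' TF; expression is promoted from the B-bound complex, occurs
#' spontaneously from a free gene (gene b's spontaneous rate is the low
#' 0.05), and is silenced while A occupies the operator.  A and B decay
#' by first-order degradation; the degradation rate of A is the
#' uncertain constant of interest.  The construction yields a CTMC with
#' 1078 states and 5919 transitions.
#'
#' B's positive autoregulation makes the circuit bistable: the canonical
#' hypotheses ask for stabilisation of B in the low mode (`B <= 2`) or
#' the high mode (`B >= 8`) over the window [500, 1000] s, in a
#' globally-operator form and in cumulative-reward form.
#'
#' @param gamma_A_interval Uncertainty interval of A's degradation rate.
#' @param gamma_B Degradation rate of B (documented settings: 0.05,
#'   0.1 and 0.2).
#' @param b0 Initial population of B (A starts at 0, genes free).
#' @return A `stochrob_fixture` with `rewards` (indicator reward
#'   structures `low`, `high`).
#' @export
gene_regulation <- function(gamma_A_interval = c(0.005, 0.5), gamma_B = 0.1,
                            b0 = 2) {
  net <- reaction_network(
    species = list(
      species("A", 10), species("B", 10),
      species("a", 1), species("aB", 1), species("aA", 1),
      species("b", 1), species("bB", 1), species("bA", 1)),
    reactions = list(
      # operator-site binding: either TF, mutually exclusive
      reaction(c(a = 1, B = 1), c(aB = 1), mass_action("k_bind"), "a+B"),
      reaction(c(aB = 1), c(a = 1, B = 1), mass_action("k_rel"), "aB-"),
      reaction(c(a = 1, A = 1), c(aA = 1), mass_action("k_bind"), "a+A"),
      reaction(c(aA = 1), c(a = 1, A = 1), mass_action("k_rel"), "aA-"),
      reaction(c(b = 1, B = 1), c(bB = 1), mass_action("k_bind"), "b+B"),
      reaction(c(bB = 1), c(b = 1, B = 1), mass_action("k_rel"), "bB-"),
      reaction(c(b = 1, A = 1), c(bA = 1), mass_action("k_bind"), "b+A"),
      reaction(c(bA = 1), c(b = 1, A = 1), mass_action("k_rel"), "bA-"),
      # expression: promoted from B-bound complexes, spontaneous from
      # free genes (gene b's spontaneous mode has the low rate)
      reaction(c(aB = 1), c(aB = 1, A = 1), mass_action("k_p"), "expr_aB"),
      reaction(c(a = 1), c(a = 1, A = 1), mass_action("k_p"), "expr_a"),
      reaction(c(bB = 1), c(bB = 1, B = 1), mass_action("k_p"), "expr_bB"),
      reaction(c(b = 1), c(b = 1, B = 1), mass_action("k_bas"), "expr_b"),
      # first-order degradation of the free proteins
      reaction(c(A = 1), integer(), mass_action("gamma_A"), "deg_A"),
      reaction(c(B = 1), integer(), mass_action("gamma_B"), "deg_B")),
    constants = list(k_bind = 1, k_rel = 1, k_p = 1, k_bas = 0.05,
                     gamma_A = gamma_A_interval, gamma_B = gamma_B),
    initial_states = list(c(a = 1, b = 1, B = b0)),
    labels = c(low = "B <= 2", high = "B >= 8"))
  props <- list(
    low_globally = prob_op(path_globally(csl_atomic("B <= 2"), 500, 1000)),
    low_reward = reward_op("low", t2 = 1000, t1 = 500),
    high_reward = reward_op("high", t2 = 1000, t1 = 500))
  structure(list(name = "gene_regulation", network = net, properties = props,
                 rewards = list(low = "B <= 2", high = "B >= 8")),
            class = "stochrob_fixture")
}

#' Two-component signalling fixture (reduced scale)
#'
#' Histidine kinase H is phosphorylated to Hp at a rate proportional to
#' the input signal S; the phospho-group is transferred to the response
#' regulator R, producing the output Rp.  Dephosphorylation of Rp is
#' spontaneous in the `basic` topology and additionally catalysed by
#' unphosphorylated H in the `modified` topology (exactly one extra
#' reaction).  Both components are produced under sigmoid (Hill)
#' regulation of their respective totals H+Hp and R+Rp around the
#' midpoint `theta` and degrade at a common first-order rate; the Hill
#' coefficients n_H and n_R control how strongly the production is
#' regulated (n = 0 is the unregulated constant rate k_max/2).
#'
#' Populations are truncated by caps on the totals H+Hp and R+Rp.  The
#' defaults are a desk-scale reduction (caps 10/10, theta 5) that keeps
#' the state space small while preserving the qualitative noise trends;
#' the regulated mean total equals theta.
#'
#' @param topology `"basic"` or `"modified"`.
#' @param signal_interval Interval (or point) for the input signal S.
#' @param n_interval Interval for the shared Hill coefficient when
#'   `merge_n = TRUE` (the default), else for both n_H and n_R.
#' @param cap_H,cap_R Truncation caps on H+Hp and R+Rp.
#' @param theta Sigmoid midpoint on the totals.
#' @param k_max Maximal production rate (per component).
#' @param gamma Common degradation rate of all four forms.
#' @param k_transfer Phosphotransfer rate constant.
#' @param k_dephos Spontaneous Rp dephosphorylation rate constant.
#' @param k_cat Catalysed dephosphorylation rate constant (modified).
#' @param merge_n Merge n_H and n_R into a single constant `n`.
#' @return A `stochrob_fixture`; canonical property: mean quadratic
#'   deviation of Rp at the stabilisation time.
#' @export
two_component <- function(topology = c("basic", "modified"),
                          signal_interval = c(0.1, 1),
                          n_interval = c(0, 20),
                          cap_H = 10, cap_R = 10, theta = 5,
                          k_max = 1, gamma = 0.1, k_transfer = 1,
                          k_dephos = 1, k_cat = 1, merge_n = TRUE) {
  topology <- match.arg(topology)
  nH <- if (merge_n) "n" else "n_H"
  nR <- if (merge_n) "n" else "n_R"
  consts <- list(S = signal_interval, k_max = k_max, gamma = gamma,
                 k_t = k_transfer, k_d = k_dephos)
  if (merge_n) consts$n <- n_interval else {
    consts$n_H <- n_interval; consts$n_R <- n_interval
  }
  rxns <- list(
    reaction(c(H = 1), c(Hp = 1), mass_action("S"), "phosphorylation"),
    reaction(c(Hp = 1, R = 1), c(H = 1, Rp = 1), mass_action("k_t"),
             "phosphotransfer"),
    reaction(c(Rp = 1), c(R = 1), mass_action("k_d"), "dephosphorylation"),
    reaction(products = c(H = 1),
             rate = sigmoid_production("k_max", c("H", "Hp"), theta, nH),
             name = "production_H"),
    reaction(products = c(R = 1),
             rate = sigmoid_production("k_max", c("R", "Rp"), theta, nR),
             name = "production_R"),
    reaction(c(H = 1), integer(), mass_action("gamma"), "deg_H"),
    reaction(c(Hp = 1), integer(), mass_action("gamma"), "deg_Hp"),
    reaction(c(R = 1), integer(), mass_action("gamma"), "deg_R"),
    reaction(c(Rp = 1), integer(), mass_action("gamma"), "deg_Rp"))
  if (topology == "modified") {
    consts$k_c <- k_cat
    rxns <- c(rxns, list(
      reaction(c(H = 1, Rp = 1), c(H = 1, R = 1), mass_action("k_c"),
               "catalysed_dephosphorylation")))
  }
  net <- reaction_network(
    species = list(species("H", cap_H), species("Hp", cap_H),
                   species("R", cap_R), species("Rp", cap_R)),
    reactions = rxns,
    constants = consts,
    initial_states = list(c(H = min(theta, cap_H), R = min(theta, cap_R))),
    total_bounds = list(list(species = c("H", "Hp"), max = cap_H),
                        list(species = c("R", "Rp"), max = cap_R)))
  props <- list(noise_Rp = mqd_op("Rp", t = 60))
  structure(list(name = paste0("two_component_", topology), network = net,
                 properties = props),
            class = "stochrob_fixture")
}

#' @export
print.stochrob_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "'\n", sep = "")
  print(x$network)
  cat("  canonical properties:", paste(names(x$properties), collapse = ", "),
      "\n")
  invisible(x)
}
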
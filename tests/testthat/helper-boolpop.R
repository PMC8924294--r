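# shared helpers: structural AST comparison, random expression corpus,
# closed forms

ast_of <- function(e) boolpop:::bp_ast(e)

expect_same_ast <- function(a, b) {
  expect_identical(ast_of(a), ast_of(b))
}

# random expression generator for round-trip property tests
random_expr <- function(depth = 3, nodes = c("A", "B", "C"),
                        vars = c("k", "mu"), dialect = "update") {
  leaf <- function() {
    pick <- sample(4, 1)
    if (pick == 1) sample(nodes, 1)
    else if (pick == 2) paste0("$", sample(vars, 1))
    else if (pick == 3) format(round(stats::runif(1, 0, 9), 2))
    else sprintf("p[(%s) = (%d)]", sample(nodes, 1), sample(0:1, 1))
  }
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.3) return(leaf())
    op <- sample(c("&", "|", "^", "+", "-", "*", "<", ">=", "=", "?", "!"), 1)
    if (op == "!") sprintf("!(%s)", build(d - 1))
    else if (op == "?") sprintf("(%s) ? (%s) : (%s)", build(d - 1), build(d - 1), build(d - 1))
    else sprintf("(%s) %s (%s)", build(d - 1), op, build(d - 1))
  }
  build(depth)
}

telegraph_p <- function(u, d, t) u / (u + d) * (1 - exp(-(u + d) * t))

# marginal of every node from an explicit state-probability vector
oracle_marginals <- function(p, n_nodes) {
  bm <- boolpop:::key_bits(names(p), n_nodes)
  vapply(seq_len(n_nodes), function(j) sum(p[bm[, j] == 1]), 0)
}
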
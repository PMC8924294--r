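# Expression language shared by node logic rules, transition-rate expressions
# and population-update formulas.
#
# Dialects:
#   "logic"  -- node references, Boolean/comparison/arithmetic operators.
#   "rate"   -- logic dialect plus `@logic` (the owning node's logic rule).
#   "update" -- logic dialect plus joint-probability terms p[(A,B) = (1,0)].
#
# Precedence (loosest to tightest): ternary `? :`, OR, XOR, AND, NOT,
# comparisons, additive, multiplicative, unary minus.  Boolean values coerce
# to 1/0 in arithmetic context; nonzero numbers are truthy in Boolean context.

bp_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bp_error")))
}

bp_parse_error <- function(msg) bp_error(msg, "bp_parse_error")
bp_eval_error <- function(msg) bp_error(msg, "bp_eval_error")
bp_validation_error <- function(msg) bp_error(msg, "bp_validation_error")

# --- tokenizer ---------------------------------------------------------------

.bp_token_patterns <- list(
  c("LOGIC", "^@logic\\b"),
  c("VAR",   "^\\$[A-Za-z_][A-Za-z0-9_]*"),
  c("NAME",  "^[A-Za-z_][A-Za-z0-9_]*"),
  c("NUM",   "^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"),
  c("OP",    "^(!=|<=|>=|==|&&|\\|\\|)"),
  c("OP",    "^[?:|&^!=<>+*/,()\\[\\]-]")
)

bp_tokenize <- function(text) {
  types <- character()
  texts <- character()
  poss <- integer()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest, perl = TRUE))
    if (length(ws) == 1L) {
      i <- i + nchar(ws)
      next
    }
    matched <- FALSE
    for (pat in .bp_token_patterns) {
      m <- regmatches(rest, regexpr(pat[2], rest, perl = TRUE))
      if (length(m) == 1L) {
        tok <- m
        typ <- pat[1]
        # normalize doubled/alternate spellings
        if (typ == "OP") {
          tok <- switch(tok, "&&" = "&", "||" = "|", "==" = "=", tok)
        }
        types <- c(types, typ)
        texts <- c(texts, tok)
        poss <- c(poss, i)
        i <- i + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      bp_parse_error(sprintf("syntax error at position %d: unexpected character '%s'",
                             i, substr(text, i, i)))
    }
  }
  list(type = types, text = texts, pos = poss, n = length(types), src = text)
}

# keyword spellings normalized to operator tokens
.bp_keywords <- c(AND = "&", OR = "|", NOT = "!", XOR = "^")

# --- parser ------------------------------------------------------------------

#' Parse an expression in the model grammar
#'
#' Parses the shared expression language used for node logic rules,
#' `rate_up`/`rate_down` transition rates and population-update formulas.
#' Node names and external `$variables` are validated against the declared
#' context; `@logic` is accepted only in the `"rate"` dialect and
#' joint-probability terms `p[(A,B) = (1,0)]` only in the `"update"` dialect.
#'
#' @param text Expression string.
#' @param nodes Character vector of declared node names.
#' @param variables Character vector of declared external variable names
#'   (without the `$` prefix), or `NULL` to accept and collect any variable
#'   reference (used while reading network files, where variables are declared
#'   implicitly).
#' @param dialect One of `"logic"`, `"rate"`, `"update"`.
#' @return An abstract syntax tree of class `bp_expr`.  When `variables` is
#'   `NULL` the attribute `"variables"` lists the variable names encountered.
#' @examples
#' e <- parse_expression("innerOn ? L : outerL",
#'                       nodes = c("innerOn", "L", "outerL"), dialect = "rate")
#' deparse_expression(e)
#' @export
parse_expression <- function(text, nodes, variables = NULL,
                             dialect = c("logic", "rate", "update")) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    bp_parse_error("empty expression")
  st <- new.env(parent = emptyenv())
  st$tok <- bp_tokenize(text)
  st$i <- 1L
  st$nodes <- nodes
  st$vars <- variables
  st$seen_vars <- character()
  st$dialect <- dialect
  e <- p_ternary(st)
  if (st$i <= st$tok$n) {
    bp_parse_error(sprintf("syntax error at position %d: unexpected '%s'",
                           st$tok$pos[st$i], st$tok$text[st$i]))
  }
  class(e) <- "bp_expr"
  attr(e, "dialect") <- dialect
  if (is.null(variables)) attr(e, "variables") <- unique(st$seen_vars)
  e
}

p_peek <- function(st) {
  if (st$i > st$tok$n) return(NULL)
  list(type = st$tok$type[st$i], text = st$tok$text[st$i], pos = st$tok$pos[st$i])
}

# does the current token denote one of the operators in `ops`
# (either as symbol or keyword spelling)?
p_at_op <- function(st, ops) {
  tk <- p_peek(st)
  if (is.null(tk)) return(FALSE)
  if (tk$type == "OP" && tk$text %in% ops) return(TRUE)
  if (tk$type == "NAME" && toupper(tk$text) %in% names(.bp_keywords) &&
      .bp_keywords[[toupper(tk$text)]] %in% ops) return(TRUE)
  FALSE
}

p_take_op <- function(st) {
  tk <- p_peek(st)
  st$i <- st$i + 1L
  if (tk$type == "NAME") .bp_keywords[[toupper(tk$text)]] else tk$text
}

p_expect <- function(st, text) {
  tk <- p_peek(st)
  if (is.null(tk))
    bp_parse_error(sprintf("syntax error: expected '%s' at end of expression", text))
  if (tk$text != text)
    bp_parse_error(sprintf("syntax error at position %d: expected '%s', found '%s'",
                           tk$pos, text, tk$text))
  st$i <- st$i + 1L
  invisible(tk)
}

p_ternary <- function(st) {
  cond <- p_or(st)
  if (p_at_op(st, "?")) {
    st$i <- st$i + 1L
    yes <- p_ternary(st)
    p_expect(st, ":")
    no <- p_ternary(st)
    return(list(type = "ifelse", cond = cond, yes = yes, no = no))
  }
  cond
}

p_binary_level <- function(st, ops, nxt, type_map) {
  lhs <- nxt(st)
  while (p_at_op(st, ops)) {
    op <- p_take_op(st)
    rhs <- nxt(st)
    lhs <- list(type = type_map[[op]], lhs = lhs, rhs = rhs)
  }
  lhs
}

p_or <- function(st) p_binary_level(st, "|", p_xor, list("|" = "or"))
p_xor <- function(st) p_binary_level(st, "^", p_and, list("^" = "xor"))
p_and <- function(st) p_binary_level(st, "&", p_not, list("&" = "and"))

p_not <- function(st) {
  if (p_at_op(st, "!")) {
    # distinguish '!' from '!=': tokenizer already folds '!=' into one token
    st$i <- st$i + 1L
    return(list(type = "not", x = p_not(st)))
  }
  p_cmp(st)
}

p_cmp <- function(st) {
  lhs <- p_add(st)
  if (p_at_op(st, c("=", "!=", "<", "<=", ">", ">="))) {
    op <- p_take_op(st)
    rhs <- p_add(st)
    return(list(type = "cmp", op = op, lhs = lhs, rhs = rhs))
  }
  lhs
}

p_add <- function(st) {
  lhs <- p_mul(st)
  while (p_at_op(st, c("+", "-"))) {
    op <- p_take_op(st)
    rhs <- p_mul(st)
    lhs <- list(type = "arith", op = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

p_mul <- function(st) {
  lhs <- p_unary(st)
  while (p_at_op(st, c("*", "/"))) {
    op <- p_take_op(st)
    rhs <- p_unary(st)
    lhs <- list(type = "arith", op = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

p_unary <- function(st) {
  if (p_at_op(st, "-")) {
    st$i <- st$i + 1L
    return(list(type = "neg", x = p_unary(st)))
  }
  p_primary(st)
}

p_primary <- function(st) {
  tk <- p_peek(st)
  if (is.null(tk)) bp_parse_error("syntax error: unexpected end of expression")
  if (tk$type == "NUM") {
    st$i <- st$i + 1L
    return(list(type = "num", value = as.numeric(tk$text)))
  }
  if (tk$type == "LOGIC") {
    if (st$dialect != "rate")
      bp_parse_error(sprintf(
        "dialect violation at position %d: '@logic' is only valid in rate expressions",
        tk$pos))
    st$i <- st$i + 1L
    return(list(type = "logic"))
  }
  if (tk$type == "VAR") {
    name <- substr(tk$text, 2L, nchar(tk$text))
    if (!is.null(st$vars) && !(name %in% st$vars))
      bp_parse_error(sprintf("unknown external variable '$%s' at position %d",
                             name, tk$pos))
    st$seen_vars <- c(st$seen_vars, name)
    st$i <- st$i + 1L
    return(list(type = "var", name = name))
  }
  if (tk$type == "NAME") {
    up <- toupper(tk$text)
    if (up %in% c("TRUE", "FALSE")) {
      st$i <- st$i + 1L
      return(list(type = "num", value = as.numeric(up == "TRUE")))
    }
    nxt <- if (st$i < st$tok$n) st$tok$text[st$i + 1L] else ""
    if (tk$text == "p" && nxt == "[") return(p_prob_term(st))
    if (!(tk$text %in% st$nodes))
      bp_parse_error(sprintf("unknown identifier '%s' at position %d",
                             tk$text, tk$pos))
    st$i <- st$i + 1L
    return(list(type = "node", name = tk$text))
  }
  if (tk$text == "(") {
    st$i <- st$i + 1L
    e <- p_ternary(st)
    p_expect(st, ")")
    return(e)
  }
  bp_parse_error(sprintf("syntax error at position %d: unexpected '%s'",
                         tk$pos, tk$text))
}

# p [( A, B ) = ( 1, 0 )] -- whitespace insignificant throughout
p_prob_term <- function(st) {
  pos <- p_peek(st)$pos
  if (st$dialect != "update")
    bp_parse_error(sprintf(
      "dialect violation at position %d: p[...] terms are only valid in population-update formulas",
      pos))
  st$i <- st$i + 1L            # 'p'
  p_expect(st, "[")
  p_expect(st, "(")
  nms <- character()
  repeat {
    tk <- p_peek(st)
    if (is.null(tk) || tk$type != "NAME")
      bp_parse_error(sprintf("syntax error in p[...] term at position %d: expected node name", pos))
    if (!(tk$text %in% st$nodes))
      bp_parse_error(sprintf("unknown identifier '%s' at position %d", tk$text, tk$pos))
    nms <- c(nms, tk$text)
    st$i <- st$i + 1L
    if (p_at_op(st, ",")) { st$i <- st$i + 1L; next }
    break
  }
  p_expect(st, ")")
  p_expect(st, "=")
  p_expect(st, "(")
  vals <- integer()
  repeat {
    tk <- p_peek(st)
    if (is.null(tk) || tk$type != "NUM" || !(tk$text %in% c("0", "1")))
      bp_parse_error(sprintf("syntax error in p[...] term at position %d: expected 0 or 1", pos))
    vals <- c(vals, as.integer(tk$text))
    st$i <- st$i + 1L
    if (p_at_op(st, ",")) { st$i <- st$i + 1L; next }
    break
  }
  p_expect(st, ")")
  p_expect(st, "]")
  if (length(nms) != length(vals))
    bp_parse_error(sprintf("p[...] term at position %d: %d nodes but %d values",
                           pos, length(nms), length(vals)))
  list(type = "prob", nodes = nms, values = vals)
}

# --- evaluation --------------------------------------------------------------

bp_truthy <- function(v) v != 0

#' Evaluate a parsed expression
#'
#' Evaluates an expression against a network state, an external-variable
#' binding, and (for update formulas) a state distribution.  Boolean results
#' are returned as 1/0; nonzero numerics are treated as true in Boolean
#' context.
#'
#' @param expr A `bp_expr` (or raw AST node).
#' @param state Named numeric/logical vector of node values (0/1), or `NULL`
#'   when the expression contains no node references.
#' @param variables Named numeric vector or list of external variable values.
#' @param dist A [state_distribution()] supplying `p[...]` terms, or `NULL`.
#' @param logic AST bound to `@logic` (the owning node's logic rule), or `NULL`.
#' @return A numeric scalar.
#' @export
eval_expression <- function(expr, state = NULL, variables = list(),
                            dist = NULL, logic = NULL) {
  ev <- function(e) {
    switch(e$type,
      num = e$value,
      node = {
        v <- state[[e$name]]
        if (is.null(v) || is.na(v))
          bp_eval_error(sprintf("node '%s' has no value in the supplied state", e$name))
        as.numeric(v)
      },
      var = {
        v <- variables[[e$name]]
        if (is.null(v))
          bp_eval_error(sprintf("external variable '$%s' is unbound", e$name))
        as.numeric(v)
      },
      logic = {
        if (is.null(logic))
          bp_eval_error("'@logic' used but no logic rule bound")
        ev(logic)
      },
      not = as.numeric(!bp_truthy(ev(e$x))),
      neg = -ev(e$x),
      and = as.numeric(bp_truthy(ev(e$lhs)) && bp_truthy(ev(e$rhs))),
      or = as.numeric(bp_truthy(ev(e$lhs)) || bp_truthy(ev(e$rhs))),
      xor = as.numeric(xor(bp_truthy(ev(e$lhs)), bp_truthy(ev(e$rhs)))),
      cmp = {
        a <- ev(e$lhs); b <- ev(e$rhs)
        as.numeric(switch(e$op,
          "=" = a == b, "!=" = a != b,
          "<" = a < b, "<=" = a <= b, ">" = a > b, ">=" = a >= b))
      },
      arith = {
        a <- ev(e$lhs); b <- ev(e$rhs)
        switch(e$op,
          "+" = a + b, "-" = a - b, "*" = a * b,
          "/" = {
            if (b == 0) bp_eval_error("division by zero in expression")
            a / b
          })
      },
      ifelse = if (bp_truthy(ev(e$cond))) ev(e$yes) else ev(e$no),
      prob = {
        if (is.null(dist))
          bp_eval_error("p[...] term evaluated without a state distribution")
        joint_probability(dist, e$nodes, e$values)
      },
      bp_eval_error(sprintf("unknown AST node type '%s'", e$type))
    )
  }
  ev(expr)
}

# --- deparser ----------------------------------------------------------------

#' Render an expression AST back to model-file text
#'
#' The output reparses to a structurally identical AST; subexpressions are
#' parenthesized conservatively rather than minimally.
#'
#' @param expr A `bp_expr` or raw AST node.
#' @return A single string.
#' @export
deparse_expression <- function(expr) {
  wrap <- function(e) {
    s <- dp(e)
    if (e$type %in% c("num", "node", "var", "logic", "prob")) s
    else paste0("(", s, ")")
  }
  dp <- function(e) {
    switch(e$type,
      num = format(e$value, digits = 15, scientific = FALSE),
      node = e$name,
      var = paste0("$", e$name),
      logic = "@logic",
      not = paste0("!", wrap(e$x)),
      neg = paste0("-", wrap(e$x)),
      and = paste(wrap(e$lhs), "&", wrap(e$rhs)),
      or = paste(wrap(e$lhs), "|", wrap(e$rhs)),
      xor = paste(wrap(e$lhs), "^", wrap(e$rhs)),
      cmp = paste(wrap(e$lhs), e$op, wrap(e$rhs)),
      arith = paste(wrap(e$lhs), e$op, wrap(e$rhs)),
      ifelse = paste(wrap(e$cond), "?", wrap(e$yes), ":", wrap(e$no)),
      prob = sprintf("p[(%s) = (%s)]",
                     paste(e$nodes, collapse = ","),
                     paste(e$values, collapse = ",")),
      stop(sprintf("unknown AST node type '%s'", e$type))
    )
  }
  dp(expr)
}

# numeric literal AST, used when synthesizing defaults and perturbations
bp_num_expr <- function(value, dialect = "rate") {
  e <- list(type = "num", value = value)
  class(e) <- "bp_expr"
  attr(e, "dialect") <- dialect
  e
}

# strip class/metadata attrs so structural comparisons see only the tree
# (nested AST nodes are attribute-free plain lists; only the root is tagged)
bp_ast <- function(e) {
  attr(e, "class") <- NULL
  attr(e, "dialect") <- NULL
  attr(e, "variables") <- NULL
  e
}
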
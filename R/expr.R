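# Algebraic expression engine: parsing, analytic differentiation, and
# compilation to vectorized R closures. Every custom force and every
# integrator computation goes through this module.

# ---- AST node constructors -------------------------------------------------

node_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "constant", value = as.numeric(value)),
            class = "mm_node")
}

node_var <- function(name) {
  structure(list(kind = "variable", name = name), class = "mm_node")
}

node_unary <- function(op, child) {
  structure(list(kind = "unary", name = op, children = list(child)),
            class = "mm_node")
}

node_binary <- function(op, left, right) {
  structure(list(kind = "binary", name = op, children = list(left, right)),
            class = "mm_node")
}

node_call <- function(fname, args) {
  structure(list(kind = "call", name = fname, children = args),
            class = "mm_node")
}

is_const <- function(n, value = NULL) {
  n$kind == "constant" && (is.null(value) || n$value == value)
}

# ---- function table --------------------------------------------------------

# step(x) = 1 for x >= 0 else 0; delta(x) = 1 iff x == 0;
# select(c, a, b) = a where c != 0, b elsewhere. All three have derivative 0
# (step/delta) or pass the derivative through their branches (select), so
# piecewise energy expressions remain differentiable by convention.
.mm_step <- function(x) as.numeric(x >= 0)
.mm_delta <- function(x) as.numeric(x == 0)
.mm_select <- function(cond, a, b) {
  out <- b + 0 * cond + 0 * a   # recycle to common length
  take <- cond != 0
  out[take] <- (a + 0 * cond + 0 * b)[take]
  out
}
.mm_div <- function(a, b) {
  if (any(b == 0)) stop("division by zero in expression evaluation")
  a / b
}
.mm_log <- function(x) {
  if (any(x <= 0)) stop("log of non-positive value in expression evaluation")
  log(x)
}

# arity NA means 2 (min/max) fixed below; deriv entries are built in
# derivative_node().
.mm_function_arity <- c(
  sin = 1, cos = 1, tan = 1, asin = 1, acos = 1, atan = 1,
  sinh = 1, cosh = 1, tanh = 1, exp = 1, log = 1, sqrt = 1,
  abs = 1, floor = 1, ceil = 1, step = 1, delta = 1,
  min = 2, max = 2, select = 3
)

.mm_function_impl <- list(
  sin = sin, cos = cos, tan = tan, asin = asin, acos = acos, atan = atan,
  sinh = sinh, cosh = cosh, tanh = tanh, exp = exp, log = .mm_log,
  sqrt = sqrt, abs = abs, floor = floor, ceil = ceiling,
  step = .mm_step, delta = .mm_delta, min = pmin, max = pmax,
  select = .mm_select
)

# ---- tokenizer -------------------------------------------------------------

tokenize_expression <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest))
      if (length(m) == 0L || m == "" || m == ".")
        stop(sprintf("syntax error at position %d: malformed number", i))
      push("number", as.numeric(m), i)
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      push("ident", m, i)
      i <- i + nchar(m)
    } else if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      push(ch, ch, i)
      i <- i + 1L
    } else {
      stop(sprintf("syntax error at position %d: unexpected character '%s'",
                   i, ch))
    }
  }
  push("end", "", n + 1L)
  tokens
}

# ---- recursive-descent parser ----------------------------------------------

# Grammar (standard precedence; '^' right-associative, binding tighter than
# unary minus, so -x^2 parses as -(x^2)):
#   expr   := term (('+'|'-') term)*
#   term   := unary (('*'|'/') unary)*
#   unary  := ('-'|'+') unary | power
#   power  := atom ('^' unary)?
#   atom   := number | ident | ident '(' expr (',' expr)* ')' | '(' expr ')'
parse_single_expression <- function(text) {
  tokens <- tokenize_expression(text)
  pos <- 1L
  peek <- function() tokens[[pos]]
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (tok$type != type)
      stop(sprintf("syntax error at position %d: expected '%s', found '%s'",
                   tok$pos, type, tok$value))
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    while (peek()$type %in% c("+", "-")) {
      op <- advance()$type
      node <- node_binary(op, node, parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_unary()
    while (peek()$type %in% c("*", "/")) {
      op <- advance()$type
      node <- node_binary(op, node, parse_unary())
    }
    node
  }
  parse_unary <- function() {
    if (peek()$type == "-") { advance(); return(node_unary("-", parse_unary())) }
    if (peek()$type == "+") { advance(); return(parse_unary()) }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_atom()
    if (peek()$type == "^") {
      advance()
      return(node_binary("^", base, parse_unary()))
    }
    base
  }
  parse_atom <- function() {
    tok <- peek()
    if (tok$type == "number") { advance(); return(node_const(tok$value)) }
    if (tok$type == "ident") {
      advance()
      if (peek()$type == "(") {
        advance()
        args <- list(parse_expr())
        while (peek()$type == ",") { advance(); args[[length(args) + 1L]] <- parse_expr() }
        expect(")")
        fname <- tok$value
        if (!(fname %in% names(.mm_function_arity)))
          stop(sprintf("unknown function '%s' at position %d", fname, tok$pos))
        arity <- .mm_function_arity[[fname]]
        if (length(args) != arity)
          stop(sprintf("function '%s' expects %d argument(s), got %d",
                       fname, arity, length(args)))
        return(node_call(fname, args))
      }
      return(node_var(tok$value))
    }
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    stop(sprintf("syntax error at position %d: unexpected '%s'",
                 tok$pos, if (tok$type == "end") "end of input" else tok$value))
  }

  node <- parse_expr()
  tok <- peek()
  if (tok$type != "end")
    stop(sprintf("syntax error at position %d: unexpected '%s'",
                 tok$pos, tok$value))
  node
}

collect_variables <- function(node) {
  if (node$kind == "constant") return(character(0))
  if (node$kind == "variable") return(node$name)
  unique(unlist(lapply(node$children, collect_variables)))
}

#' Parse an algebraic energy or integrator expression
#'
#' Parses a string such as \code{"k*(theta-theta0)^2"} into an abstract
#' syntax tree. Trailing semicolon-separated segments of the form
#' \code{name=expr} define named intermediate values (used e.g. for
#' Lorentz-Berthelot combination rules in pair potentials):
#' \code{"4*eps*((sig/r)^12-(sig/r)^6); sig=0.5*(sig1+sig2); eps=sqrt(eps1*eps2)"}.
#' Definitions may reference each other in either textual order; they are
#' topologically sorted and cycles are an error.
#'
#' Supported functions: sin, cos, tan, asin, acos, atan, sinh, cosh, tanh,
#' exp, log (natural), sqrt, abs, floor, ceil, min, max, step, delta,
#' select(cond, a, b). \code{^} is right-associative and binds tighter than
#' unary minus. \code{0^0} evaluates to 1; division by zero and log of a
#' non-positive value raise an error at evaluation time.
#'
#' @param text expression string, non-empty.
#' @return an object of class \code{mm_expr} with elements \code{root}
#'   (AST), \code{definitions} (named list of ASTs in evaluation order) and
#'   \code{free_variables} (character vector).
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  segments <- strsplit(text, ";", fixed = TRUE)[[1]]
  segments <- trimws(segments)
  segments <- segments[nzchar(segments)]
  if (length(segments) == 0L) stop("empty expression")
  root <- parse_single_expression(segments[[1]])
  defs <- list()
  if (length(segments) > 1L) {
    for (seg in segments[-1]) {
      m <- regmatches(seg, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*=(.*)$", seg))[[1]]
      if (length(m) == 0L)
        stop(sprintf("malformed definition '%s' (expected name=expression)", seg))
      name <- m[[2]]
      if (name %in% names(defs))
        stop(sprintf("duplicate definition name '%s'", name))
      defs[[name]] <- parse_single_expression(m[[3]])
    }
  }
  # topological sort of definitions
  if (length(defs) > 0L) {
    dnames <- names(defs)
    deps <- lapply(defs, function(d) intersect(collect_variables(d), dnames))
    order <- character(0)
    remaining <- dnames
    while (length(remaining) > 0L) {
      ready <- remaining[vapply(remaining, function(nm)
        all(deps[[nm]] %in% order), logical(1))]
      if (length(ready) == 0L)
        stop("cyclic intermediate definitions")
      # keep textual order among ready ones for reproducibility
      ready <- remaining[remaining %in% ready]
      order <- c(order, ready)
      remaining <- setdiff(remaining, ready)
    }
    defs <- defs[order]
  }
  all_vars <- unique(c(collect_variables(root),
                       unlist(lapply(defs, collect_variables))))
  free <- setdiff(all_vars, names(defs))
  structure(list(root = root, definitions = defs, free_variables = free),
            class = "mm_expr")
}

#' @export
print.mm_expr <- function(x, ...) {
  cat("<mm_expr> ", unparse_node(x$root), "\n", sep = "")
  for (nm in names(x$definitions))
    cat("  ", nm, " = ", unparse_node(x$definitions[[nm]]), "\n", sep = "")
  cat("  free variables:", paste(x$free_variables, collapse = ", "), "\n")
  invisible(x)
}

# ---- unparse ---------------------------------------------------------------

unparse_node <- function(node) {
  switch(node$kind,
    constant = {
      v <- node$value
      if (v < 0) sprintf("(%s)", format(v, digits = 17)) else format(v, digits = 17)
    },
    variable = node$name,
    unary = sprintf("(-%s)", unparse_node(node$children[[1]])),
    binary = sprintf("(%s%s%s)", unparse_node(node$children[[1]]), node$name,
                     unparse_node(node$children[[2]])),
    call = sprintf("%s(%s)", node$name,
                   paste(vapply(node$children, unparse_node, character(1)),
                         collapse = ","))
  )
}

#' Render an expression back to a string
#'
#' The output re-parses to an AST that evaluates identically.
#' @param pe an \code{mm_expr}.
#' @return a single string, including any intermediate definitions.
#' @export
unparse_expression <- function(pe) {
  out <- unparse_node(pe$root)
  if (length(pe$definitions) > 0L)
    out <- paste(c(out, paste0(names(pe$definitions), "=",
                               vapply(pe$definitions, unparse_node, character(1)))),
                 collapse = "; ")
  out
}

# ---- direct AST interpretation --------------------------------------------

eval_node <- function(node, values) {
  switch(node$kind,
    constant = node$value,
    variable = {
      v <- values[[node$name]]
      if (is.null(v)) stop(sprintf("unbound variable '%s'", node$name))
      v
    },
    unary = -eval_node(node$children[[1]], values),
    binary = {
      a <- eval_node(node$children[[1]], values)
      b <- eval_node(node$children[[2]], values)
      switch(node$name,
             "+" = a + b, "-" = a - b, "*" = a * b,
             "/" = .mm_div(a, b), "^" = a ^ b)
    },
    call = {
      args <- lapply(node$children, eval_node, values = values)
      do.call(.mm_function_impl[[node$name]], args)
    }
  )
}

#' Evaluate a parsed expression by direct AST interpretation
#'
#' Walks the tree node by node. Slower than \code{\link{compile_expression}}
#' but with no code-generation step; the two must agree to machine precision.
#'
#' @param pe an \code{mm_expr}.
#' @param values named list of numeric vectors, one per free variable
#'   (recycled elementwise).
#' @return numeric vector.
#' @export
evaluate_expression <- function(pe, values) {
  env <- as.list(values)
  for (nm in names(pe$definitions))
    env[[nm]] <- eval_node(pe$definitions[[nm]], env)
  eval_node(pe$root, env)
}

# ---- simplification --------------------------------------------------------

node_equal <- function(a, b) identical(unclass(a), unclass(b))

#' Simplify an expression tree
#'
#' Constant folding plus the elementary identities (x+0, x*1, x*0, x^1, x^0,
#' x/1, double negation). Idempotent; the result evaluates identically to the
#' input wherever the input is defined.
#'
#' @param node an AST node (or an \code{mm_expr}, simplified recursively).
#' @return simplified node (or \code{mm_expr}).
#' @export
simplify_node <- function(node) {
  if (inherits(node, "mm_expr")) {
    node$root <- simplify_node(node$root)
    node$definitions <- lapply(node$definitions, simplify_node)
    return(node)
  }
  if (node$kind %in% c("constant", "variable")) return(node)
  node$children <- lapply(node$children, simplify_node)

  # constant folding (skip when evaluation errors, e.g. 1/0)
  if (all(vapply(node$children, is_const, logical(1)))) {
    v <- tryCatch(eval_node(node, list()), error = function(e) NULL)
    if (!is.null(v) && is.finite(v)) return(node_const(v))
  }

  if (node$kind == "unary") {
    ch <- node$children[[1]]
    if (ch$kind == "unary") return(ch$children[[1]])   # --x -> x
    return(node)
  }
  if (node$kind == "binary") {
    a <- node$children[[1]]; b <- node$children[[2]]
    op <- node$name
    if (op == "+") {
      if (is_const(a, 0)) return(b)
      if (is_const(b, 0)) return(a)
    } else if (op == "-") {
      if (is_const(b, 0)) return(a)
      if (is_const(a, 0)) return(simplify_node(node_unary("-", b)))
    } else if (op == "*") {
      if (is_const(a, 0) || is_const(b, 0)) return(node_const(0))
      if (is_const(a, 1)) return(b)
      if (is_const(b, 1)) return(a)
    } else if (op == "/") {
      if (is_const(b, 1)) return(a)
      if (is_const(a, 0)) return(node_const(0))
    } else if (op == "^") {
      if (is_const(b, 1)) return(a)
      if (is_const(b, 0)) return(node_const(1))  # 0^0 = 1 by convention
      if (is_const(a, 1)) return(node_const(1))
    }
    return(node)
  }
  node
}

# ---- differentiation -------------------------------------------------------

substitute_variables <- function(node, mapping) {
  if (node$kind == "constant") return(node)
  if (node$kind == "variable") {
    rep <- mapping[[node$name]]
    if (!is.null(rep)) return(rep)
    return(node)
  }
  node$children <- lapply(node$children, substitute_variables, mapping = mapping)
  node
}

inline_definitions <- function(pe) {
  mapping <- list()
  for (nm in names(pe$definitions))
    mapping[[nm]] <- substitute_variables(pe$definitions[[nm]], mapping)
  substitute_variables(pe$root, mapping)
}

derivative_node <- function(node, var) {
  k <- node$kind
  if (k == "constant") return(node_const(0))
  if (k == "variable") return(node_const(if (node$name == var) 1 else 0))
  if (k == "unary") return(node_unary("-", derivative_node(node$children[[1]], var)))
  if (k == "binary") {
    a <- node$children[[1]]; b <- node$children[[2]]
    da <- derivative_node(a, var); db <- derivative_node(b, var)
    return(switch(node$name,
      "+" = node_binary("+", da, db),
      "-" = node_binary("-", da, db),
      "*" = node_binary("+", node_binary("*", da, b), node_binary("*", a, db)),
      "/" = node_binary("/",
              node_binary("-", node_binary("*", da, b), node_binary("*", a, db)),
              node_binary("^", b, node_const(2))),
      "^" = {
        if (is_const(b)) {
          # power rule: c * a^(c-1) * a'
          node_binary("*", node_binary("*", b,
            node_binary("^", a, node_const(b$value - 1))), da)
        } else {
          # d(a^b) = a^b * (b' log a + b a'/a)
          node_binary("*", node,
            node_binary("+",
              node_binary("*", db, node_call("log", list(a))),
              node_binary("/", node_binary("*", b, da), a)))
        }
      }))
  }
  # function calls
  args <- node$children
  dargs <- lapply(args, derivative_node, var = var)
  x <- args[[1]]; dx <- dargs[[1]]
  chain <- function(outer) node_binary("*", outer, dx)
  switch(node$name,
    sin  = chain(node_call("cos", list(x))),
    cos  = node_unary("-", chain(node_call("sin", list(x)))),
    tan  = chain(node_binary("/", node_const(1),
             node_binary("^", node_call("cos", list(x)), node_const(2)))),
    asin = chain(node_binary("/", node_const(1),
             node_call("sqrt", list(node_binary("-", node_const(1),
               node_binary("^", x, node_const(2))))))),
    acos = node_unary("-", chain(node_binary("/", node_const(1),
             node_call("sqrt", list(node_binary("-", node_const(1),
               node_binary("^", x, node_const(2)))))))),
    atan = chain(node_binary("/", node_const(1),
             node_binary("+", node_const(1), node_binary("^", x, node_const(2))))),
    sinh = chain(node_call("cosh", list(x))),
    cosh = chain(node_call("sinh", list(x))),
    tanh = chain(node_binary("-", node_const(1),
             node_binary("^", node_call("tanh", list(x)), node_const(2)))),
    exp  = chain(node_call("exp", list(x))),
    log  = node_binary("/", dx, x),
    sqrt = node_binary("/", dx, node_binary("*", node_const(2), node)),
    abs  = chain(node_binary("-", node_binary("*", node_const(2),
             node_call("step", list(x))), node_const(1))),
    floor = node_const(0),
    ceil  = node_const(0),
    step  = node_const(0),
    delta = node_const(0),
    min  = node_call("select", list(
             node_call("step", list(node_binary("-", args[[2]], args[[1]]))),
             dargs[[1]], dargs[[2]])),
    max  = node_call("select", list(
             node_call("step", list(node_binary("-", args[[1]], args[[2]]))),
             dargs[[1]], dargs[[2]])),
    select = node_call("select", list(args[[1]], dargs[[2]], dargs[[3]])),
    stop(sprintf("no derivative rule for function '%s'", node$name))
  )
}

#' Analytically differentiate a parsed expression
#'
#' Returns an expression algebraically equal to the partial derivative of
#' \code{pe} with respect to \code{var}, with the chain rule applied through
#' intermediate definitions (which are inlined first). \code{step},
#' \code{delta}, \code{floor} and \code{ceil} have derivative 0 by
#' convention; \code{min}/\code{max}/\code{select} differentiate through the
#' selected branch.
#'
#' @param pe an \code{mm_expr}.
#' @param var name of a free variable of \code{pe}.
#' @return an \code{mm_expr} (no definitions) equal to d pe / d var.
#' @export
differentiate_expression <- function(pe, var) {
  if (!(var %in% pe$free_variables))
    stop(sprintf("'%s' is not a free variable of the expression", var))
  inlined <- inline_definitions(pe)
  d <- simplify_node(derivative_node(inlined, var))
  structure(list(root = d, definitions = list(),
                 free_variables = collect_variables(d)),
            class = "mm_expr")
}

# ---- compilation -----------------------------------------------------------

node_to_lang <- function(node) {
  switch(node$kind,
    constant = node$value,
    variable = as.name(node$name),
    unary = call("-", node_to_lang(node$children[[1]])),
    binary = {
      a <- node_to_lang(node$children[[1]])
      b <- node_to_lang(node$children[[2]])
      if (node$name == "/") call(".mm_div", a, b)
      else call(node$name, a, b)
    },
    call = {
      args <- lapply(node$children, node_to_lang)
      fname <- switch(node$name, ceil = "ceiling", log = ".mm_log",
                      min = "pmin", max = "pmax", step = ".mm_step",
                      delta = ".mm_delta", select = ".mm_select", node$name)
      as.call(c(as.name(fname), args))
    }
  )
}

compile_env <- function() {
  env <- new.env(parent = baseenv())
  env$.mm_div <- .mm_div
  env$.mm_log <- .mm_log
  env$.mm_step <- .mm_step
  env$.mm_delta <- .mm_delta
  env$.mm_select <- .mm_select
  env
}

#' Compile a parsed expression into a pure vectorized R function
#'
#' Generates an R closure whose body is the translated expression (with
#' intermediate definitions as local bindings), byte-compiled on first call
#' by R's JIT. The function is pure and evaluates elementwise over aligned
#' numeric vectors; batch evaluation agrees with scalar evaluation to
#' machine precision.
#'
#' @param pe an \code{mm_expr}.
#' @param input_order character vector naming the arguments, a superset of
#'   the expression's free variables.
#' @return a function taking \code{length(input_order)} numeric arguments.
#' @export
compile_expression <- function(pe, input_order = pe$free_variables) {
  missing <- setdiff(pe$free_variables, input_order)
  if (length(missing) > 0L)
    stop(sprintf("input_order is missing variable(s): %s",
                 paste(missing, collapse = ", ")))
  stmts <- lapply(seq_along(pe$definitions), function(i)
    call("<-", as.name(names(pe$definitions)[i]),
         node_to_lang(pe$definitions[[i]])))
  body <- as.call(c(as.name("{"), stmts, list(node_to_lang(pe$root))))
  formals <- stats::setNames(replicate(length(input_order), quote(expr = )),
                             input_order)
  f <- eval(call("function", as.pairlist(formals), body), compile_env())
  attr(f, "input_names") <- input_order
  f
}

# convenience: parse + substitute global parameter constants
substitute_constants <- function(pe, constants) {
  if (length(constants) == 0L) return(pe)
  mapping <- lapply(constants, node_const)
  pe$root <- substitute_variables(pe$root, mapping)
  pe$definitions <- lapply(pe$definitions, substitute_variables,
                           mapping = mapping)
  pe$free_variables <- setdiff(pe$free_variables, names(constants))
  pe
}
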
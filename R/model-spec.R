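#' Build a model from a declarative specification
#'
#' User models are written as a plain list (or YAML/JSON file) of rate
#' expressions instead of R code. The specification has fields:
#'
#' * `name` — model name;
#' * `states` — character vector of state labels;
#' * `parameters` — character vector of estimated parameter labels;
#' * `constants` — named list of fixed quantities (optional);
#' * `odes` — named list mapping each state to the expression (a string) for
#'   its time derivative; expressions may use states, parameters, constants,
#'   the stimulus `u` and time `t`;
#' * `initial` — named list mapping each state to the expression for its
#'   value at t = 0 (parameters and constants only); missing states start
#'   at 0;
#' * `readouts` — named list mapping each readout label to its expression in
#'   states and parameters (optional; identity readouts for every state are
#'   always added).
#'
#' Every expression is checked to reference only declared symbols.
#'
#' @param spec A list as described above, or a path to a YAML/JSON file
#'   containing one.
#' @return A [dynamic_model()].
#' @export
model_from_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    spec <- if (grepl("\\.json$", spec, ignore.case = TRUE)) {
      jsonlite::read_json(spec, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(spec)
    }
  }
  states <- as.character(spec$states)
  params <- as.character(spec$parameters)
  constants <- as.list(spec$constants %||% list())
  allowed <- c(states, params, names(constants), "u", "t")

  parse_checked <- function(txt, where, extra_forbidden = character(0)) {
    ex <- str2lang(txt)
    vars <- all.vars(ex)
    bad <- setdiff(vars, setdiff(allowed, extra_forbidden))
    if (length(bad)) {
      abort(paste0(where, " references undefined symbol(s): ",
                   paste(bad, collapse = ", ")),
            class = "plsens_config_error")
    }
    ex
  }

  ode_txt <- spec$odes
  if (!setequal(names(ode_txt), states)) {
    abort("odes must define exactly one expression per state",
          class = "plsens_config_error")
  }
  ode_exprs <- lapply(states, function(s)
    parse_checked(ode_txt[[s]], paste0("ode for ", s)))

  init_txt <- spec$initial %||% list()
  init_exprs <- lapply(states, function(s) {
    if (!is.null(init_txt[[s]])) {
      parse_checked(as.character(init_txt[[s]]), paste0("initial state of ", s),
                    extra_forbidden = c(states, "u", "t"))
    } else {
      quote(0)
    }
  })

  readout_txt <- as.list(spec$readouts %||% list())
  readout_exprs <- lapply(names(readout_txt), function(lab)
    parse_checked(as.character(readout_txt[[lab]]), paste0("readout ", lab)))
  names(readout_exprs) <- names(readout_txt)

  # expressions are compiled to plain closures: state symbols become
  # x[["s"]] / x[, "s"] and parameter symbols p[["name"]], so repeated
  # evaluation allocates no environments
  subst_symbols <- function(ex, map) {
    if (is.symbol(ex)) {
      nm <- as.character(ex)
      if (!is.null(map[[nm]])) return(map[[nm]])
      return(ex)
    }
    if (is.call(ex)) {
      for (i in seq_along(ex)[-1]) ex[[i]] <- subst_symbols(ex[[i]], map)
    }
    ex
  }
  par_syms <- c(params, names(constants))
  scalar_map <- c(
    lapply(setNames(states, states), function(s)
      bquote(x[[.(s)]])),
    lapply(setNames(par_syms, par_syms), function(s)
      bquote(p[[.(s)]]))
  )
  column_map <- c(
    lapply(setNames(states, states), function(s)
      bquote(x[, .(s)])),
    lapply(setNames(par_syms, par_syms), function(s)
      bquote(p[[.(s)]]))
  )
  fn_of <- function(args, body_expr) {
    eval(call("function", as.pairlist(args), body_expr), baseenv())
  }
  rhs_body <- as.call(c(quote(c), lapply(ode_exprs, subst_symbols, scalar_map)))
  rhs_core <- fn_of(alist(t = , x = , p = , u = ), rhs_body)
  rhs <- function(t, x, p, u) setNames(rhs_core(t, x, p, u), states)
  init_body <- as.call(c(quote(c), lapply(init_exprs, subst_symbols, scalar_map)))
  init_core <- fn_of(alist(p = ), init_body)
  initial_state <- function(p) setNames(init_core(p), states)
  readouts <- lapply(states, function(s) {
    force(s)
    function(x, p) as.numeric(x[, s])
  })
  names(readouts) <- states
  for (lab in names(readout_exprs)) {
    readouts[[lab]] <- fn_of(alist(x = , p = ),
                             subst_symbols(readout_exprs[[lab]], column_map))
  }

  dynamic_model(name = spec$name %||% "model", states = states, params = params,
                rhs = rhs, initial_state = initial_state, readouts = readouts,
                constants = constants, spec = spec)
}

#' Write a model's declarative specification to YAML
#'
#' Only models built from a specification (including the two bundled models)
#' can be exported; hand-written R models carry no symbolic form.
#'
#' @param model A [dynamic_model()] with a stored `spec`.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  if (is.null(model$spec)) {
    abort("model has no declarative specification to export",
          class = "plsens_config_error")
  }
  yaml::write_yaml(model$spec, path)
  invisible(path)
}

#' Look up a bundled model by name
#'
#' @param name `"insilico4"` (four-species mass-action network) or
#'   `"dsalina"` (chlorophyll fluorescence induction model).
#' @return A [dynamic_model()].
#' @export
model_library <- function(name) {
  switch(name,
    insilico4 = insilico_model(),
    dsalina = dsalina_model(),
    abort(paste0("unknown bundled model: ", name), class = "plsens_config_error")
  )
}
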
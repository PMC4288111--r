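# Deterministic generators of synthetic application ontologies, class
# hierarchies and instance populations.  The defaults emulate the deployed
# registries the engine targets: projects collect a few hundred to 2000
# cases with roughly 60 to 600 variables per case, organized as a case root
# plus per-topic forms (manifestations, precipitating factors, laboratory,
# treatment...).  Everything is seed-deterministic.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic registry generator
#'
#' Defaults sit inside the envelope of deployed projects: `n_cases` in the
#' few-hundreds (projects range from a few hundred to 2000) and total
#' variables per case (`n_data_structures` times mean fields per structure)
#' inside 60--600.
#'
#' @param n_data_structures Number of forms, including the case root.
#' @param fields_per_structure Integer range (min, max) of fields per form.
#' @param n_cases Default population size for [populate_instances()].
#' @param option_list_fraction Fraction of fields constrained by an
#'   AllowedValues option list.
#' @param reportable_fraction Fraction of non-root forms whose creations are
#'   notified (Reportable subclasses).
#' @param dependent_fraction Fraction of menu links flagged
#'   directly-dependent (cascade on delete).
#' @param seed Integer seed; equal seeds give byte-identical fixtures.
#' @return A `registry_params` list.
#' @export
registry_params <- function(n_data_structures = 8,
                            fields_per_structure = c(6, 12),
                            n_cases = 300,
                            option_list_fraction = 0.3,
                            reportable_fraction = 0.25,
                            dependent_fraction = 0.5,
                            seed = 1) {
  stopifnot(n_data_structures >= 1, length(fields_per_structure) == 2,
            fields_per_structure[1] >= 1,
            fields_per_structure[2] >= fields_per_structure[1],
            n_cases >= 0, seed == as.integer(seed))
  structure(list(n_data_structures = as.integer(n_data_structures),
                 fields_per_structure = as.integer(fields_per_structure),
                 n_cases = as.integer(n_cases),
                 option_list_fraction = option_list_fraction,
                 reportable_fraction = reportable_fraction,
                 dependent_fraction = dependent_fraction,
                 seed = as.integer(seed)),
            class = "registry_params")
}

DS_NAME_POOL <- c("Precipitating_Factors", "Previous_Manifestations",
                  "Clinical_Manifestations", "Laboratory", "Treatment",
                  "Cardiac_Involvement", "Renal_Involvement",
                  "Adrenal_Involvement", "Pulmonary_Involvement",
                  "Neurologic_Involvement", "Demographics", "Outcome",
                  "Adverse_Events", "Followup", "Serology", "Imaging")

#' Generate a synthetic application ontology
#'
#' Produces a registry that passes [validate_application()] with zero
#' errors: a case-root DataStructure, menu object properties to the other
#' forms, a mix of all widget kinds (every widget and every facet appears at
#' least once under default parameters, including one unsupported SubForm
#' field, which validates as a warning), at least one CodedValues option
#' list, and Reportable / directly-dependent structures as requested.
#'
#' @param params A [registry_params()] list.
#' @return A [statement_set()] (the application model ontology).
#' @export
generate_registry <- function(params = registry_params()) {
  if (params$n_data_structures < 1) stop("need at least the case root form")
  with_seed(params$seed, generate_registry_impl(params))
}

generate_registry_impl <- function(params) {
  ns <- paste0("http://ontoreg.org/fixtures/registry", params$seed)
  A <- function(local) paste0(ns, "#", local)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- stmt(...)
  addl <- function(...) rows[[length(rows) + 1L]] <<- lit_stmt(...)
  add(ns, IRI_TYPE, IRI_ONTOLOGY)
  add(ns, IRI_IMPORTS, METAMODEL_IRI)
  add(A("Registry"), IRI_TYPE, IRI_CLASS)
  add(A("Registry"), IRI_TYPE, MM("Application"))
  n_ds <- params$n_data_structures
  ds_names <- c("Case",
                if (n_ds > 1) c(utils::head(DS_NAME_POOL, n_ds - 1L),
                                if (n_ds - 1L > length(DS_NAME_POOL))
                                  paste0("Section_",
                                         seq_len(n_ds - 1L -
                                                   length(DS_NAME_POOL)))))
  n_report <- round(params$reportable_fraction * (n_ds - 1L))
  reportable <- if (n_ds > 1 && n_report > 0)
    ds_names[-1][seq_len(n_report)] else character(0)
  for (d in ds_names) {
    add(A(d), IRI_TYPE, IRI_CLASS)
    add(A(d), IRI_TYPE, MM("DataStructure"))
    add(A(d), IRI_SUBCLASS, MM("ApplicationItem"))
    if (d %in% reportable) add(A(d), IRI_SUBCLASS, MM("Reportable"))
  }
  # widget assignment: a fixed cycle guarantees full coverage (SubForm once),
  # then a weighted draw
  cycle <- setdiff(FORM_WIDGETS, "SubForm")
  cycle <- c(cycle, "SubForm")
  widget_i <- 0L
  draw_pool <- c("SingleCell", "SingleCell", "SingleCell", "Checkbox",
                 "Combobox", "RadioButton", "MultilineStringProperty",
                 "HyperlinkProperty")
  next_widget <- function() {
    widget_i <<- widget_i + 1L
    if (widget_i <= length(cycle)) return(cycle[widget_i])
    w <- sample(draw_pool, 1L)
    if (stats::runif(1) < params$option_list_fraction) {
      w <- sample(c("Combobox", "RadioButton"), 1L)
    }
    w
  }
  singlecell_tags <- c("string", "integer", "float", "date", "datetime")
  sc_i <- 0L
  coded_done <- FALSE
  edition_done <- FALSE
  for (di in seq_along(ds_names)) {
    d <- ds_names[di]
    k <- sample(seq(params$fields_per_structure[1],
                    params$fields_per_structure[2]), 1L)
    for (j in seq_len(k)) {
      f <- A(paste0("f_", tolower(d), "_", j))
      row <- ceiling(j / 2); col <- ((j - 1L) %% 2L) + 1L
      if (j == 1L) {
        # id field: unique, mandatory, part of the description
        add(f, IRI_TYPE, IRI_DTPROP)
        add(f, IRI_TYPE, MM("SingleCell"))
        add(f, IRI_DOMAIN, A(d))
        add(f, IRI_RANGE, XSD("string"))
        addl(f, MM("webRow"), row, "integer")
        addl(f, MM("webColumn"), col, "integer")
        addl(f, MM("webIdProperty"), "true", "boolean")
        addl(f, MM("webMandatoryProperty"), "true", "boolean")
        addl(f, MM("webDescriptionProperty"), "true", "boolean")
        next
      }
      w <- next_widget()
      choice <- w %in% CHOICE_WIDGETS
      add(f, IRI_TYPE, if (choice) IRI_OBJPROP else IRI_DTPROP)
      add(f, IRI_TYPE, MM(w))
      add(f, IRI_DOMAIN, A(d))
      addl(f, MM("webRow"), row, "integer")
      addl(f, MM("webColumn"), col, "integer")
      if (choice) {
        av <- A(paste0("AV_", tolower(d), "_", j))
        use_coded <- !coded_done || stats::runif(1) < 0.4
        coded_done <- TRUE
        add(av, IRI_TYPE, IRI_CLASS)
        add(av, IRI_SUBCLASS, MM(if (use_coded) "CodedValues" else
          "AllowedValues"))
        add(f, IRI_RANGE, av)
        n_opt <- sample(3:6, 1L)
        for (oi in seq_len(n_opt)) {
          opt <- A(paste0("opt_", tolower(d), "_", j, "_", oi))
          add(opt, IRI_TYPE, av)
          addl(opt, IRI_LABEL, paste0(gsub("_", " ", d), " option ", oi),
               "string")
          addl(opt, MM("order"), oi, "integer")
          if (use_coded) addl(opt, MM("code"), sprintf("C%02d", oi), "string")
        }
      } else {
        tag <- switch(w,
          Checkbox = "boolean",
          SingleCell = { sc_i <<- sc_i + 1L
            singlecell_tags[((sc_i - 1L) %% length(singlecell_tags)) + 1L] },
          "string")
        add(f, IRI_RANGE, XSD(tag))
      }
      if (w %in% c("SingleCell", "Checkbox", "MultilineStringProperty") &&
          stats::runif(1) < 0.25) {
        addl(f, MM("webMandatoryProperty"), "true", "boolean")
      }
      if (w %in% c("SingleCell", "MultilineStringProperty") &&
          stats::runif(1) < 0.3) {
        addl(f, MM("webDescriptionProperty"), "true", "boolean")
      }
      if (!edition_done && di > 1L && w == "SingleCell") {
        addl(f, MM("webEditionDisabled"), "true", "boolean")
        edition_done <- TRUE
      }
    }
  }
  # menu object properties from the case root to every other form
  n_dep <- round(params$dependent_fraction * (n_ds - 1L))
  dep <- if (n_ds > 1 && n_dep > 0) ds_names[-1][seq_len(n_dep)] else
    character(0)
  for (d in ds_names[-1]) {
    m <- A(paste0("menu_", tolower(d)))
    add(m, IRI_TYPE, IRI_OBJPROP)
    add(m, IRI_TYPE, MM("MenuItem"))
    add(m, IRI_DOMAIN, A("Case"))
    add(m, IRI_RANGE, A(d))
    addl(m, IRI_LABEL, gsub("_", " ", d), "string")
    if (d %in% dep) addl(m, MM("webDirectlyDependent"), "true", "boolean")
  }
  # extraction specifications: the case root recursively, the first child
  # form flat
  ex1 <- A("extract_case")
  add(ex1, IRI_TYPE, MM("DataExtraction"))
  add(ex1, MM("extractionClass"), A("Case"))
  addl(ex1, MM("recursive"), "true", "boolean")
  if (n_ds > 1) {
    ex2 <- A(paste0("extract_", tolower(ds_names[2])))
    add(ex2, IRI_TYPE, MM("DataExtraction"))
    add(ex2, MM("extractionClass"), A(ds_names[2]))
    addl(ex2, MM("recursive"), "false", "boolean")
  }
  statement_set(rows, ns)
}

#' Parameters for the synthetic class-hierarchy generator
#'
#' @param n_classes Number of classes; the deep-taxonomy stress preset used
#'   in the batch-build checks is 15982 classes.
#' @param max_depth,branching Shape controls for the random forest.
#' @param multiparent_fraction Fraction of classes receiving a second parent
#'   (multiple inheritance), honored to within one class.
#' @param seed Integer seed.
#' @return A `hierarchy_params` list.
#' @export
hierarchy_params <- function(n_classes = 200, max_depth = 8, branching = 3,
                             multiparent_fraction = 0.1, seed = 1) {
  stopifnot(n_classes >= 1, max_depth >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 max_depth = as.integer(max_depth),
                 branching = as.integer(branching),
                 multiparent_fraction = multiparent_fraction,
                 seed = as.integer(seed)),
            class = "hierarchy_params")
}

#' Generate a random acyclic subsumption hierarchy
#'
#' A rooted forest (single root) grown under a depth cap, then a fraction of
#' nodes receive one extra parent drawn among lower-numbered nodes, which
#' keeps the edge set acyclic by construction.
#'
#' @param params A [hierarchy_params()] list.
#' @return A data.frame of `child` / `parent` resource ids (empty for
#'   `n_classes = 1`).
#' @export
generate_hierarchy <- function(params = hierarchy_params()) {
  with_seed(params$seed, {
    n <- params$n_classes
    if (n == 1L) {
      return(data.frame(child = integer(0), parent = integer(0)))
    }
    depth <- integer(n); depth[1] <- 1L
    parent <- integer(n)
    child_count <- integer(n)
    for (i in 2:n) {
      eligible <- which(depth[seq_len(i - 1L)] < params$max_depth &
                          child_count[seq_len(i - 1L)] < params$branching)
      if (!length(eligible)) eligible <- which.min(depth[seq_len(i - 1L)])
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      parent[i] <- p
      depth[i] <- depth[p] + 1L
      child_count[p] <- child_count[p] + 1L
    }
    edges <- data.frame(child = 2:n, parent = parent[2:n])
    n_multi <- round(params$multiparent_fraction * n)
    cand <- which(seq_len(n) >= 3L)
    if (n_multi > 0 && length(cand)) {
      extra <- sample(cand, min(n_multi, length(cand)))
      for (x in extra) {
        choices <- setdiff(seq_len(x - 1L), parent[x])
        if (length(choices)) {
          p2 <- if (length(choices) == 1L) choices else sample(choices, 1L)
          edges <- rbind(edges, data.frame(child = x, parent = p2))
        }
      }
    }
    edges
  })
}

#' Populate a loaded application with synthetic instances
#'
#' Creates `params$n_cases` case instances plus linked child records per menu
#' entry, all through [create_instance()] (so the generated values must and
#' do satisfy every facet constraint), and links children to their cases.
#'
#' @param repo An `ontoreg_repo` with the application uploaded.
#' @param app_ns Application (model) namespace.
#' @param params A [registry_params()] list (uses `n_cases` and `seed`).
#' @return Summary list: `cases` (ids), `children` (count per form),
#'   invisibly.
#' @export
populate_instances <- function(repo, app_ns, params = registry_params()) {
  with_seed(params$seed * 7919L + 13L,
            populate_impl(repo, app_ns, params))
}

populate_impl <- function(repo, app_ns, params) {
  app <- download_ontology(repo, app_ns)
  model <- compile_forms(app)
  case_ds <- model$case_root
  dns <- data_namespace(app_ns)
  case_ids <- integer(0)
  children <- integer(0)
  if (params$n_cases == 0L) {
    return(invisible(list(cases = case_ids, children = children)))
  }
  for (ci in seq_len(params$n_cases)) {
    vals <- draw_values(model$forms[[case_ds]],
                        id_value = sprintf("CASE-%d-%05d", params$seed, ci))
    cid <- create_instance(repo, case_ds, vals)
    case_ids <- c(case_ids, cid)
    for (mi in seq_len(nrow(model$menu))) {
      target <- model$menu$target[mi]
      k <- sample(0:2, 1L)
      for (kk in seq_len(k)) {
        vals2 <- draw_values(model$forms[[target]],
                             id_value = sprintf("%s-%d-%05d-%d",
                                                iri_local(target),
                                                params$seed, ci, kk))
        child <- create_instance(repo, target, vals2)
        assert_statement(repo, stmt(res_iri_of(repo, cid),
                                    model$menu$property[mi],
                                    res_iri_of(repo, child), "iri"),
                         ns = dns)
        children[target] <- (if (is.na(children[target])) 0L else
          children[[target]]) + 1L
      }
    }
  }
  invisible(list(cases = case_ids, children = children))
}

#' Generate a populated registry dump as statements
#'
#' Builds the application model plus a synthetic instance population
#' expressed directly as statements under the data namespace -- the shape of
#' a full registry dump, used to exercise the bulk ingestion path at the
#' scale of deployed projects (on the order of 100,000 statements).  Unlike
#' [populate_instances()] this does not go through the CRUD gate; the values
#' are drawn from the same constraint-respecting distributions.
#'
#' @param params A [registry_params()] list.
#' @return A list of two [statement_set()]s: `model` and `data`.
#' @export
generate_registry_dump <- function(params = registry_params()) {
  app <- generate_registry(params)
  with_seed(params$seed * 104729L + 7L, {
    model <- compile_forms(app)
    ns <- ss_ontology_iri(app)
    dns <- data_namespace(ns)
    cap <- 4096L; nr <- 0L
    S <- character(cap); P <- character(cap); O <- character(cap)
    K <- character(cap); Tg <- character(cap)
    push <- function(s, p, o, k, tg) {
      nr <<- nr + 1L
      if (nr > cap) {
        cap <<- 2L * cap
        length(S) <<- cap; length(P) <<- cap; length(O) <<- cap
        length(K) <<- cap; length(Tg) <<- cap
      }
      S[nr] <<- s; P[nr] <<- p; O[nr] <<- o; K[nr] <<- k; Tg[nr] <<- tg
    }
    counter <- 0L
    make_inst <- function(ds, id_value) {
      counter <<- counter + 1L
      iri <- paste0(dns, "#", iri_local(ds), "_", counter)
      push(iri, IRI_TYPE, ds, "iri", NA_character_)
      vals <- draw_values(model$forms[[ds]], id_value)
      form <- model$forms[[ds]]
      spec_of <- stats::setNames(form$fields,
                                 vapply(form$fields, function(s) s$property,
                                        character(1)))
      for (p in names(vals)) {
        s <- spec_of[[p]]
        for (x in vals[[p]]) {
          if (!is.null(s$options)) {
            hit <- match(x, s$options$label)
            push(iri, p, s$options$iri[hit], "iri", NA_character_)
          } else {
            tag <- if (is.na(s$value_tag)) "string" else s$value_tag
            push(iri, p, as.character(x), "literal", tag)
          }
        }
      }
      iri
    }
    for (ci in seq_len(params$n_cases)) {
      case <- make_inst(model$case_root,
                        sprintf("CASE-%d-%05d", params$seed, ci))
      for (mi in seq_len(nrow(model$menu))) {
        for (kk in seq_len(sample(0:2, 1L))) {
          child <- make_inst(model$menu$target[mi],
                             sprintf("%s-%d-%05d-%d",
                                     iri_local(model$menu$target[mi]),
                                     params$seed, ci, kk))
          push(case, model$menu$property[mi], child, "iri", NA_character_)
        }
      }
    }
    idx <- seq_len(nr)
    data_ss <- statement_set(data.frame(
      subject = S[idx], predicate = P[idx], object = O[idx],
      obj_kind = K[idx], lit_type = Tg[idx], stringsAsFactors = FALSE), dns)
    list(model = app, data = data_ss)
  })
}

draw_values <- function(form, id_value) {
  vals <- list()
  for (s in form$fields) {
    if (identical(s$widget, "LiteralProperty")) next
    if (isTRUE(s$facets$is_id)) { vals[[s$property]] <- id_value; next }
    mandatory <- isTRUE(s$facets$is_mandatory)
    if (!mandatory && stats::runif(1) > 0.7) next
    v <- if (!is.null(s$options)) {
      sample(s$options$label, 1L)
    } else if (identical(s$widget, "Password")) {
      sprintf("pw_%06d", sample.int(1e6, 1L))
    } else {
      switch(if (is.na(s$value_tag)) "string" else s$value_tag,
        string = sprintf("text_%05d", sample.int(99999L, 1L)),
        integer = sample.int(120L, 1L),
        float = round(stats::runif(1) * 100, 2),
        boolean = sample(c("true", "false"), 1L),
        date = as.character(as.Date("2005-01-01") + sample.int(6000L, 1L)),
        datetime = paste0(as.character(as.Date("2005-01-01") +
                                         sample.int(6000L, 1L)),
                          "T", sprintf("%02d:%02d:00",
                                       sample.int(24L, 1L) - 1L,
                                       sample.int(60L, 1L) - 1L)))
    }
    vals[[s$property]] <- v
  }
  vals
}
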
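# CellML reader: documents, MathML, connections, metadata.

fixture_path <- function() {
  system.file("extdata", "basic_membrane_synthetic.cellml",
              package = "cellmlgen")
}

test_that("a tagged voltage variable parses with units and initial value", {
  m <- parse_cellml(fixture_path())
  v <- get_tagged_variable(m, "membrane_voltage")
  expect_identical(v$name, "V")
  expect_identical(v$units, "millivolt")
  expect_identical(v$init, -80)
  expect_identical(v$kind, "state")
  expect_identical(get_tagged_variable(m, "time")$name, "time")
  # piecewise and e-notation constants survive parsing
  f <- model_rhs_function(m)
  y <- model_initial_state(m)
  expect_identical(unname(f(0, y)), 0.5)   # pulse active before t = 10
  expect_identical(unname(f(20, y)), 0)    # and off after
})

test_that("parsing is deterministic and initial evaluation is finite", {
  m1 <- parse_cellml(fixture_path())
  m2 <- parse_cellml(fixture_path())
  # identical structure and ordering (units registries are environments and
  # compared by contents)
  expect_identical(m1[c("name", "variables", "equations", "states",
                        "free_variable")],
                   m2[c("name", "variables", "equations", "states",
                        "free_variable")])
  expect_setequal(ls(m1$units), ls(m2$units))
  gm <- generate_model(generator_spec(seed = 5))
  tf <- withr::local_tempfile(fileext = ".cellml")
  write_cellml(gm$model, tf)
  m <- parse_cellml(tf)
  expect_true(all(is.finite(model_rhs_function(m)(0,
                                                  model_initial_state(m)))))
})

test_that("the Hodgkin-Huxley fixture round-trips with seven components", {
  hh <- make_hh_1952_fixture()
  tf <- withr::local_tempfile(fileext = ".cellml")
  write_cellml(hh, tf)
  m <- parse_cellml(tf)
  expect_length(unique(vapply(m$variables, `[[`, "", "component")), 7L)
  expect_setequal(m$states, hh$states)
  # numerically identical right-hand sides at a probe point
  y <- model_initial_state(hh)
  y["V"] <- -33.3
  d1 <- model_rhs_function(hh)(1, y)
  d2 <- model_rhs_function(m)(1, y)
  expect_identical(unname(d2[names(d1)]), unname(d1))
})

test_that("version and structural errors are explicit", {
  bad <- withr::local_tempfile(fileext = ".cellml")
  writeLines(paste0(
    "<model xmlns=\"http://www.cellml.org/cellml/2.0#\" name=\"x\">",
    "</model>"
  ), bad)
  expect_error(parse_cellml(bad), "unsupported CellML version")

  writeLines("<model name='x'><component", bad)
  expect_error(parse_cellml(bad))

  writeLines(paste0(
    "<model xmlns=\"http://www.cellml.org/cellml/1.0#\" name=\"x\">",
    "<component name=\"c\">",
    "<variable name=\"a\" units=\"dimensionless\"/>",
    "</component></model>"
  ), bad)
  expect_error(parse_cellml(bad), "neither a defining equation nor")

  writeLines(paste0(
    "<model xmlns=\"http://www.cellml.org/cellml/1.0#\" name=\"x\">",
    "<import/></model>"
  ), bad)
  expect_error(parse_cellml(bad), "unsupported CellML element <import>")
})

test_that("MathML equations translate to operator trees", {
  scope <- c(a = "a", b = "b", t = "t", V = "V")
  eq <- parse_mathml(xml2::read_xml(
    "<apply><eq/><ci>a</ci><apply><plus/><ci>b</ci><cn>1</cn></apply></apply>"
  ), scope)
  expect_false(eq$ode)
  expect_true(expr_identical(eq$rhs, expr_parse("b + 1")))

  eq <- parse_mathml(xml2::read_xml(paste0(
    "<apply><eq/>",
    "<apply><diff/><bvar><ci>t</ci></bvar><ci>V</ci></apply>",
    "<apply><times/><cn>2</cn><ci>V</ci></apply></apply>"
  )), scope)
  expect_true(eq$ode)
  expect_identical(eq$lhs, "V")

  eq <- parse_mathml(xml2::read_xml(paste0(
    "<apply><eq/><ci>a</ci><piecewise>",
    "<piece><cn>1</cn><apply><lt/><ci>V</ci><cn>0</cn></apply></piece>",
    "<otherwise><cn>2</cn></otherwise></piecewise></apply>"
  )), scope)
  expect_identical(call_name <- as.character(eq$rhs[[1]]), "piecewise")
  expect_length(as.list(eq$rhs), 4L) # cond, value, otherwise + head

  expect_error(parse_mathml(xml2::read_xml(
    "<apply><eq/><ci>a</ci><apply><csymbol/><ci>b</ci></apply></apply>"
  ), scope), "unsupported MathML element <csymbol>")

  expect_error(parse_mathml(xml2::read_xml(
    "<apply><eq/><ci>a</ci><ci>zz</ci></apply>"
  ), scope), "undefined variable 'zz'")
})

test_that("connections collapse equivalence classes with one definition", {
  comps <- list(
    A = list(name = "A", variables = list(
      V = list(name = "V", initial_value = -80, public_interface = "out")
    )),
    B = list(name = "B", variables = list(
      V = list(name = "V", initial_value = NA, public_interface = "in")
    )),
    C = list(name = "C", variables = list(
      V = list(name = "V", initial_value = NA, public_interface = "in")
    ))
  )
  conns <- list(
    list(component_1 = "A", variable_1 = "V",
         component_2 = "B", variable_2 = "V"),
    list(component_1 = "B", variable_1 = "V",
         component_2 = "C", variable_2 = "V")
  )
  cm <- resolve_connections(comps, conns)
  expect_length(unique(cm$class_of), 1L)
  expect_identical(unname(unlist(cm$canonical)), "A.V")

  comps$B$variables$V$initial_value <- -70
  expect_error(resolve_connections(comps, conns),
               "both carry initial values")
})

test_that("RDF annotations map cmeta ids to ontology tags", {
  doc <- xml2::read_xml(paste0(
    "<model xmlns=\"http://www.cellml.org/cellml/1.0#\" ",
    "xmlns:cmeta=\"http://www.cellml.org/metadata/1.0#\" name=\"m\">",
    "<component name=\"c\">",
    "<variable name=\"V\" units=\"volt\" initial_value=\"0\" ",
    "cmeta:id=\"vid\"/></component>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" ",
    "xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
    "<rdf:Description rdf:about=\"#vid\">",
    "<bqbiol:is rdf:resource=\"http://x#membrane_voltage\"/>",
    "<bqbiol:is rdf:resource=\"http://x#derived_quantity\"/>",
    "</rdf:Description>",
    "<rdf:Description rdf:about=\"#ghost\">",
    "<bqbiol:is rdf:resource=\"http://x#time\"/>",
    "</rdf:Description>",
    "</rdf:RDF></model>"
  ))
  expect_warning(tags <- extract_metadata_tags(doc), "missing cmeta:id")
  expect_named(tags, "vid")
  expect_setequal(tags$vid, c("membrane_voltage", "derived_quantity"))

  empty <- xml2::read_xml("<model name=\"m\"/>")
  expect_identical(extract_metadata_tags(empty), list())
})
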
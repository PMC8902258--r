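<?xml version="1.0" encoding="UTF-8"?>
<!-- Small synthetic fixture: a leaky membrane relaxing to rest, with a
     voltage variable annotated via RDF in the Web Lab style. -->
<model name="basic_membrane" cmeta:id="basic_membrane"
    xmlns="http://www.cellml.org/cellml/1.0#"
    xmlns:cellml="http://www.cellml.org/cellml/1.0#"
    xmlns:cmeta="http://www.cellml.org/metadata/1.0#">
  <units name="millisecond">
    <unit units="second" prefix="milli"/>
  </units>
  <units name="millivolt">
    <unit units="volt" prefix="milli"/>
  </units>
  <component name="environment">
    <variable name="time" units="millisecond" public_interface="out"
        cmeta:id="time"/>
  </component>
  <component name="membrane">
    <variable name="time" units="millisecond" public_interface="in"/>
    <variable name="V" units="millivolt" initial_value="-80"
        public_interface="out" cmeta:id="membrane_voltage"/>
    <variable name="V_rest" units="millivolt" initial_value="-80"/>
    <variable name="tau" units="millisecond" initial_value="10"/>
    <variable name="pulse" units="millivolt"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <ci>pulse</ci>
        <piecewise>
          <piece>
            <cn cellml:units="millivolt">5</cn>
            <apply><lt/><ci>time</ci>
              <cn cellml:units="millisecond" type="e-notation">1<sep/>1</cn>
            </apply>
          </piece>
          <otherwise><cn cellml:units="millivolt">0</cn></otherwise>
        </piecewise>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply>
        <apply><divide/>
          <apply><plus/>
            <apply><minus/><ci>V_rest</ci><ci>V</ci></apply>
            <ci>pulse</ci>
          </apply>
          <ci>tau</ci>
        </apply>
      </apply>
    </math>
  </component>
  <connection>
    <map_components component_1="environment" component_2="membrane"/>
    <map_variables variable_1="time" variable_2="time"/>
  </connection>
  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
      xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
    <rdf:Description rdf:about="#membrane_voltage">
      <bqbiol:is
        rdf:resource="https://chaste.comlab.ox.ac.uk/cellml/ns/oxford-metadata#membrane_voltage"/>
    </rdf:Description>
    <rdf:Description rdf:about="#time">
      <bqbiol:is
        rdf:resource="https://chaste.comlab.ox.ac.uk/cellml/ns/oxford-metadata#time"/>
    </rdf:Description>
  </rdf:RDF>
</model>
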
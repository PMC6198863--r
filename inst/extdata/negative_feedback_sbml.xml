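<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="negative_feedback">
    <listOfCompartments>
      <compartment id="cell" size="1" spatialDimensions="3" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cell" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="false"/>
      <species id="X" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="Y" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="4" constant="true"/>
      <parameter id="k2" value="0.80000000000000004" constant="true"/>
      <parameter id="k3" value="0.40000000000000002" constant="true"/>
      <parameter id="k4" value="0.25" constant="true"/>
      <parameter id="ki" value="0.20000000000000001" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="production_X" reversible="false" fast="false">
        <listOfProducts>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <divide/>
              <apply>
                <times/>
                <ci>k1</ci>
                <ci>S</ci>
              </apply>
              <apply>
                <plus/>
                <cn type="real">1</cn>
                <apply>
                  <divide/>
                  <ci>Y</ci>
                  <ci>ki</ci>
                </apply>
              </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="decay_X" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k2</ci>
              <ci>X</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="production_Y" reversible="false" fast="false">
        <listOfProducts>
          <speciesReference species="Y" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k3</ci>
              <ci>X</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="decay_Y" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="Y" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k4</ci>
              <ci>Y</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
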
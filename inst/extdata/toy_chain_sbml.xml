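<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="glucose" compartment="e" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="g6p_c" name="glucose-6-phosphate" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="pyr_c" name="pyruvate" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ten" value="10" constant="true"/>
      <parameter id="hundred" value="100" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_glc" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfProducts>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: exchange</p></body></notes>
      </reaction>
      <reaction id="T_glc" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="hundred">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g1"/>
        </fbc:geneProductAssociation>
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: transport</p></body></notes>
      </reaction>
      <reaction id="GLYC" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="hundred">
        <listOfReactants>
          <speciesReference species="g6p_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
          </fbc:and>
        </fbc:geneProductAssociation>
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: glycolysis</p></body></notes>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="pyr_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: biomass</p></body></notes>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
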
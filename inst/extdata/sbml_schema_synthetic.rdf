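<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic RDFS fragment in the style of an SBML vocabulary: a class
     hierarchy (KineticLaw < SBMLElement < Element) and a property
     (kineticLaw < sbmlElement) with domain Reaction and range KineticLaw.
     The namespace IRI is a synthetic placeholder. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:sbmlRdf="http://sbml.org/sbmlRdf#">
  <rdfs:Class rdf:about="http://sbml.org/sbmlRdf#Element"/>
  <rdfs:Class rdf:about="http://sbml.org/sbmlRdf#SBMLElement">
    <rdfs:subClassOf rdf:resource="http://sbml.org/sbmlRdf#Element"/>
  </rdfs:Class>
  <rdfs:Class rdf:about="http://sbml.org/sbmlRdf#SpeciesReference">
    <rdfs:subClassOf rdf:resource="http://sbml.org/sbmlRdf#SBMLElement"/>
  </rdfs:Class>
  <rdfs:Class rdf:about="http://sbml.org/sbmlRdf#KineticLaw">
    <rdfs:subClassOf rdf:resource="http://sbml.org/sbmlRdf#SBMLElement"/>
  </rdfs:Class>
  <rdfs:Class rdf:about="http://sbml.org/sbmlRdf#Reaction"/>
  <rdf:Property rdf:about="http://sbml.org/sbmlRdf#sbmlElement"/>
  <rdf:Property rdf:about="http://sbml.org/sbmlRdf#kineticLaw">
    <rdfs:subPropertyOf rdf:resource="http://sbml.org/sbmlRdf#sbmlElement"/>
    <rdfs:domain rdf:resource="http://sbml.org/sbmlRdf#Reaction"/>
    <rdfs:range rdf:resource="http://sbml.org/sbmlRdf#KineticLaw"/>
  </rdf:Property>
</rdf:RDF>
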